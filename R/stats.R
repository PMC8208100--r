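#' Unpaired two-sample t test
#'
#' Two-tailed Student's t with pooled variance by default (Welch via
#' `welch = TRUE`), as used for projection-neuron vs unlabelled-neuron group
#' comparisons.
#'
#' @param group_a,group_b Numeric vectors, n >= 2 each.
#' @param welch Use the Welch correction instead of pooled variance.
#' @return A `comparison_result` list: test, statistic, df, p_value, and
#'   per-group n / mean / sd.
#' @export
unpaired_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    res <- list(statistic = 0, parameter = length(group_a) + length(group_b) - 2,
                p.value = 1)
  } else {
    res <- stats::t.test(group_a, group_b, var.equal = !welch)
  }
  comparison_result(
    test = if (welch) "Welch t" else "Student t (pooled)",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    groups = data.frame(
      group = c("a", "b"),
      n = c(length(group_a), length(group_b)),
      mean = c(mean(group_a), mean(group_b)),
      sd = c(stats::sd(group_a), stats::sd(group_b))
    )
  )
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction (matching the usual incidence-table usage for
#' discharge-pattern, AHP-profile and subthreshold-current distributions). A
#' warning flag is set when any expected count falls below 5.
#'
#' @param table Matrix of non-negative counts (e.g. 2 x m).
#' @return A `comparison_result`; `low_expected` flags expected counts < 5.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  out <- comparison_result(
    test = "Pearson chi-squared",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    groups = NULL
  )
  out$low_expected <- any(res$expected < 5)
  out
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups List of numeric vectors (one per group, each n >= 2);
#'   typically the per-cluster values of one feature.
#' @return A `comparison_result` with the F statistic, plus `$tukey`: a data
#'   frame of pairwise differences and adjusted p values.
#' @export
anova_tukey <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  out <- comparison_result(
    test = "one-way ANOVA",
    statistic = an[["F value"]][1L],
    df = c(an[["Df"]][1L], an[["Df"]][2L]),
    p_value = an[["Pr(>F)"]][1L],
    groups = data.frame(
      group = names(groups),
      n = vapply(groups, length, 1L),
      mean = vapply(groups, mean, 1),
      sd = vapply(groups, stats::sd, 1),
      row.names = NULL
    )
  )
  out$tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL)
  out
}

comparison_result <- function(test, statistic, df, p_value, groups) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, groups = groups),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Percentage from a count pair
#'
#' @param positive,total Non-negative counts with `positive <= total`,
#'   `total > 0`.
#' @param rounding `"integer"` (nearest whole percent) or `"one_decimal"`.
#' @return Percentage on the 0-100 scale.
#' @export
proportion_from_counts <- function(positive, total,
                                   rounding = c("integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  if (total <= 0) stop("total must be > 0", call. = FALSE)
  if (positive < 0 || positive > total) {
    stop("need 0 <= positive <= total", call. = FALSE)
  }
  pct <- 100 * positive / total
  if (rounding == "integer") round(pct) else round(pct, 1L)
}

#' Build a cohort summary report
#'
#' Mirrors the usual reporting layer of a patch-clamp cohort study: group
#' means +/- sd for each feature, discharge-pattern incidence by identity,
#' and cluster composition with purity.
#'
#' @param table A [feature_table()] (imputed or not).
#' @param identities Character vector aligned with the table rows
#'   (e.g. `"SPBN"` / `"UN"`).
#' @param calls Optional character vector of discharge-pattern calls.
#' @param cluster_labels Optional integer cluster labels.
#' @return A list of data frames: `feature_summary`, `incidence`,
#'   `cluster_composition`.
#' @export
build_report <- function(table, identities, calls = NULL,
                         cluster_labels = NULL) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$values)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  if (length(identities) != n) stop("identities misaligned", call. = FALSE)
  vals <- table$values
  vals[table$mask] <- NA
  feature_summary <- do.call(rbind, lapply(unique(identities), function(id) {
    sub <- vals[identities == id, , drop = FALSE]
    data.frame(identity = id, feature = colnames(sub),
               n = colSums(!is.na(sub)),
               mean = colMeans(sub, na.rm = TRUE),
               sd = apply(sub, 2L, stats::sd, na.rm = TRUE),
               row.names = NULL)
  }))
  incidence <- NULL
  if (!is.null(calls)) {
    if (length(calls) != n) stop("calls misaligned", call. = FALSE)
    tab <- table(identity = identities, pattern = calls)
    incidence <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(incidence)[3L] <- "count"
  }
  cluster_composition <- NULL
  if (!is.null(cluster_labels)) {
    if (length(cluster_labels) != n) stop("cluster labels misaligned",
                                          call. = FALSE)
    pur <- cluster_purity(cluster_labels, identities)
    cluster_composition <- pur
  }
  list(feature_summary = feature_summary, incidence = incidence,
       cluster_composition = cluster_composition)
}
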