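#' Default clustering feature panel
#'
#' The 20 continuous per-cell electrophysiological parameters entered into
#' the Euclidean/Ward clustering. Discharge-pattern and AHP-profile categories
#' are dendrogram annotations, not distance features.
#'
#' @return Character vector of feature names.
#' @export
default_feature_panel <- function() {
  c("Cm_pF", "Rin_MOhm", "RMP_mV", "rheobase_pA",
    "ap_threshold_mV", "ap_peak_amplitude_mV", "ap_rise_ms",
    "ap_base_width_ms", "ahp_amplitude_mV", "ahp_latency_ms",
    "first_spike_latency_ms", "mean_frequency_Hz",
    "mean_instantaneous_frequency_Hz", "adaptation", "attenuation_pct",
    "discharge_duration_ms", "sepsc_frequency_Hz", "sepsc_amplitude_pA",
    "sepsc_tau_ms", "subthreshold_peak_pA")
}

#' Assemble a feature table from per-cell feature records
#'
#' @param records Named list (one element per cell) of named numeric vectors
#'   of features; `NA` marks features undefined for that cell.
#' @param features Feature names to keep, default [default_feature_panel()].
#' @param impute Impute missing entries with the per-feature median
#'   (missingness stays recorded in the mask).
#' @return A [feature_table()].
#' @export
assemble_feature_table <- function(records, features = default_feature_panel(),
                                   impute = TRUE) {
  if (!length(records)) stop("no cell records supplied", call. = FALSE)
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("cell_", seq_along(records))
  vals <- matrix(NA_real_, nrow = length(records), ncol = length(features),
                 dimnames = list(ids, features))
  for (i in seq_along(records)) {
    rec <- unlist(records[[i]])
    found <- intersect(features, names(rec))
    vals[i, found] <- as.numeric(rec[found])
  }
  absent <- colSums(!is.na(vals)) == 0L
  if (any(absent)) {
    stop("feature(s) absent from every cell: ",
         paste(features[absent], collapse = ", "), call. = FALSE)
  }
  mask <- is.na(vals)
  if (impute) {
    for (j in seq_len(ncol(vals))) {
      if (any(mask[, j])) {
        vals[mask[, j], j] <- stats::median(vals[, j], na.rm = TRUE)
      }
    }
  }
  feature_table(vals, cell_ids = ids, feature_names = features, mask = mask)
}

#' Min-max normalise a feature matrix
#'
#' Maps each column to [0, 1] (the heatmap convention: per-property maximum
#' and minimum). A constant column carries no contrast and is mapped to 0.5
#' with a warning. Idempotent.
#'
#' @param x Numeric matrix or [feature_table()].
#' @return Object of the same kind with normalised values.
#' @export
minmax_normalize <- function(x) {
  if (inherits(x, "feature_table")) {
    out <- x
    out$values <- minmax_normalize(x$values)
    return(out)
  }
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    if (diff(rng) == 0) {
      warning("constant column ", j, " mapped to 0.5", call. = FALSE)
      x[, j] <- 0.5
    } else {
      x[, j] <- (x[, j] - rng[1L]) / diff(rng)
    }
  }
  x
}

#' Ward hierarchical clustering on Euclidean distances
#'
#' Agglomerative merges minimising the increase in total within-cluster sum
#' of squares, with the standard Lance-Williams convention in which a
#' singleton pair merges at its Euclidean distance (height^2 = 2 x SSE
#' increase).
#'
#' @param x Numeric matrix (rows = cells), no missing values.
#' @return An object of class `"cluster_tree"` wrapping the merge list,
#'   heights, dendrogram leaf order and labels.
#' @export
ward_linkage <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (anyNA(x)) stop("missing values must be imputed before clustering",
                     call. = FALSE)
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = if (is.null(hc$labels)) as.character(seq_len(nrow(x)))
                  else hc$labels,
         n = nrow(x), method = "ward.D2", hclust = hc),
    class = "cluster_tree"
  )
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> Ward linkage, %d leaves, top height %.4g\n",
              x$n, max(x$height)))
  invisible(x)
}

#' Cut a cluster tree into k groups
#'
#' @param tree A [ward_linkage()] tree.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Integer label vector (1..k) named by leaf labels.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (k < 1L || k > tree$n) stop("k out of range", call. = FALSE)
  stats::cutree(tree$hclust, k = k)
}

#' Silhouette-based cluster-number selection
#'
#' For each k in 2..kmax, per-sample silhouettes s(i) = (b - a)/max(a, b) are
#' computed on the Euclidean distances of the supplied (normalised) matrix.
#' The chosen k is the largest k such that no silhouette is negative at any
#' cut up to k while the k+1 cut introduces a negative one -- the point where
#' additional clusters stop accounting for variability. If no cut up to kmax
#' produces a negative silhouette the mean-silhouette maximiser is reported
#' with a `"no negative found"` flag; if even the 2-cluster cut has negative
#' silhouettes, a single cluster is reported.
#'
#' @param x Numeric matrix used for the distances (normalise first; see
#'   [minmax_normalize()]).
#' @param tree Matching [ward_linkage()] tree.
#' @param kmax Largest k examined (default 8, capped at n - 1).
#' @return A `"cluster_result"` list: `chosen_k`, `labels` (matrix, one
#'   column per k), `silhouettes` (list of per-sample widths), `mean_sil`,
#'   `flag`.
#' @export
silhouette_select_k <- function(x, tree, kmax = 8) {
  stopifnot(inherits(tree, "cluster_tree"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  kmax <- min(kmax, n - 1L)
  d <- stats::dist(x, method = "euclidean")
  ks <- 2:kmax
  labels <- vapply(ks, function(k) cut_tree(tree, k), integer(n))
  colnames(labels) <- paste0("k", ks)
  sils <- lapply(seq_along(ks), function(i) {
    sw <- cluster::silhouette(labels[, i], d)
    as.numeric(sw[, "sil_width"])
  })
  names(sils) <- colnames(labels)
  has_neg <- vapply(sils, function(s) any(s < 0), TRUE)
  mean_sil <- vapply(sils, mean, 1)
  flag <- NULL
  if (!any(has_neg)) {
    chosen <- ks[which.max(mean_sil)]
    flag <- "no negative found"
  } else if (has_neg[1L]) {
    chosen <- 1L
    flag <- "negative silhouettes already at k = 2"
  } else {
    first_neg <- min(which(has_neg))       # index into ks
    chosen <- ks[first_neg - 1L]
  }
  structure(
    list(chosen_k = as.integer(chosen), k_examined = ks, labels = labels,
         silhouettes = sils, mean_sil = mean_sil, flag = flag),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> chosen k = %d%s\n", x$chosen_k,
              if (is.null(x$flag)) "" else paste0(" (", x$flag, ")")))
  print(round(x$mean_sil, 3))
  invisible(x)
}

#' Export a cluster tree as a Newick string
#'
#' Midpoint convention: node depth = merge height / 2, leaves at depth 0, so
#' two leaves merged at height h appear as `(A:h/2,B:h/2);`. Leaf names that
#' contain Newick metacharacters are single-quoted.
#'
#' @param tree A [ward_linkage()] tree.
#' @param labels Optional replacement leaf labels (e.g. cell id annotated
#'   with pattern code and identity).
#' @return Newick string (terminated by `;`).
#' @export
export_dendrogram_newick <- function(tree, labels = tree$labels) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (length(labels) != tree$n) stop("labels length mismatch", call. = FALSE)
  esc <- function(s) {
    if (grepl("[][():;,'\"[:space:]]", s)) {
      paste0("'", gsub("'", "''", s), "'")
    } else s
  }
  depth <- function(node) if (node < 0) 0 else tree$height[node] / 2
  build <- function(node, edge_len) {
    if (node < 0) {   # leaf
      sprintf("%s:%s", esc(labels[-node]), format(edge_len, digits = 10))
    } else {
      h <- tree$height[node] / 2
      kids <- tree$merge[node, ]
      sprintf("(%s,%s):%s",
              build(kids[1L], h - depth(kids[1L])),
              build(kids[2L], h - depth(kids[2L])),
              format(edge_len, digits = 10))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root] / 2
  kids <- tree$merge[root, ]
  sprintf("(%s,%s);",
          build(kids[1L], h - depth(kids[1L])),
          build(kids[2L], h - depth(kids[2L])))
}

#' Per-cluster identity purity
#'
#' @param labels Cluster labels.
#' @param identities Aligned identity vector (e.g. `"SPBN"` / `"UN"`).
#' @return Data frame: cluster, n, majority identity, majority count,
#'   purity_pct.
#' @export
cluster_purity <- function(labels, identities) {
  if (length(labels) != length(identities)) {
    stop("labels and identities must be aligned", call. = FALSE)
  }
  tab <- table(labels, identities)
  stopifnot(all(rowSums(tab) > 0))   # empty clusters impossible by construction
  data.frame(
    cluster = rownames(tab),
    n = as.integer(rowSums(tab)),
    majority = colnames(tab)[apply(tab, 1L, which.max)],
    majority_n = as.integer(apply(tab, 1L, max)),
    purity_pct = 100 * apply(tab, 1L, max) / rowSums(tab),
    row.names = NULL
  )
}
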