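## Bundle layout: one directory per cell holding `metadata.json` plus one CSV
## matrix per protocol group (rows = samples, columns = sweeps). Numbers are
## written with 17 significant digits so a write-then-read round trip is
## bit-exact for IEEE doubles. Diffable and language-neutral by design.

#' Write a cell record as a bundle directory
#'
#' @param cell A [cell_record()].
#' @param path Directory to create (must not already contain a bundle unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing bundle.
#' @return `path`, invisibly.
#' @export
write_cell_bundle <- function(cell, path, overwrite = FALSE) {
  stopifnot(inherits(cell, "cell_record"))
  if (dir.exists(path) && file.exists(file.path(path, "metadata.json")) &&
      !overwrite) {
    stop("bundle already exists at ", path, call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "spinephys-bundle",
    version = 1L,
    cell_id = cell$cell_id,
    identity = cell$identity,
    lamina = cell$lamina,
    slice_plane = cell$slice_plane,
    bias_current_pA = cell$bias_current_pA,
    groups = lapply(cell$sweeps, function(grp) {
      list(
        dt = grp[[1L]]$dt,
        units = grp[[1L]]$units,
        n_sweeps = length(grp),
        sweeps = lapply(grp, function(sw) {
          list(epochs = sw$epochs, meta = sw$meta)
        })
      )
    })
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  for (g in names(cell$sweeps)) {
    mat <- vapply(cell$sweeps[[g]], `[[`, numeric(length(cell$sweeps[[g]][[1L]]$samples)),
                  "samples")
    mat <- matrix(mat, ncol = length(cell$sweeps[[g]]))
    write_numeric_csv(mat, file.path(path, paste0(g, ".csv")),
                      col_names = paste0("sweep_", seq_len(ncol(mat))))
  }
  invisible(path)
}

#' Read a cell bundle directory
#'
#' @param path Directory written by [write_cell_bundle()] (or any tool
#'   emitting the documented layout).
#' @return A validated [cell_record()].
#' @export
read_cell_bundle <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) {
    stop("not a bundle: missing metadata.json in ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  for (fld in c("cell_id", "identity", "lamina", "slice_plane")) {
    if (is.null(meta[[fld]])) {
      stop("bundle metadata missing field '", fld, "'", call. = FALSE)
    }
  }
  groups <- names(meta$groups)
  bad <- setdiff(groups, PROTOCOL_GROUPS)
  if (length(bad)) {
    stop("bundle declares unknown protocol group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweeps <- list()
  for (g in groups) {
    gm <- meta$groups[[g]]
    if (is.null(gm$dt) || is.null(gm$units)) {
      stop("group '", g, "' is missing dt or units", call. = FALSE)
    }
    mat <- read_numeric_csv(file.path(path, paste0(g, ".csv")))
    n_declared <- gm$n_sweeps
    if (!is.null(n_declared) && ncol(mat) != n_declared) {
      stop("group '", g, "': CSV has ", ncol(mat), " sweeps, metadata says ",
           n_declared, call. = FALSE)
    }
    sweeps[[g]] <- lapply(seq_len(ncol(mat)), function(i) {
      sm <- gm$sweeps[[i]]
      ep <- NULL
      if (!is.null(sm$epochs) && length(sm$epochs)) {
        ep <- do.call(rbind, lapply(sm$epochs, function(e) {
          data.frame(start_ms = e$start_ms, duration_ms = e$duration_ms,
                     command_level = e$command_level, kind = e$kind,
                     stringsAsFactors = FALSE)
        }))
      }
      sweep_trace(mat[, i], dt = gm$dt, units = gm$units, epochs = ep,
                  meta = if (is.null(sm$meta)) list() else
                    lapply(sm$meta, function(v) if (is.list(v)) unlist(v) else v))
    })
  }
  cell_record(cell_id = meta$cell_id, identity = meta$identity,
              lamina = meta$lamina, slice_plane = meta$slice_plane,
              sweeps = sweeps, bias_current_pA = meta$bias_current_pA %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## 17 significant digits round-trip IEEE doubles exactly
write_numeric_csv <- function(mat, path, col_names) {
  txt <- apply(mat, 2L, function(col) formatC(col, digits = 17, format = "g"))
  txt <- matrix(trimws(txt), ncol = ncol(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(col_names, collapse = ","), con)
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
  invisible(path)
}

read_numeric_csv <- function(path) {
  if (!file.exists(path)) stop("missing sweep matrix: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}

#' Write a feature table to CSV
#'
#' Header row holds feature names; first column the cell id; masked (missing)
#' values are written as empty fields.
#'
#' @param table A [feature_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  vals <- table$values
  vals[table$mask] <- NA_real_
  txt <- apply(vals, 2L, function(col) {
    out <- trimws(formatC(col, digits = 17, format = "g"))
    out[is.na(col)] <- ""
    out
  })
  txt <- matrix(txt, ncol = ncol(vals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell_id", table$feature_names), collapse = ","), con)
  writeLines(paste(table$cell_ids,
                   apply(txt, 1L, paste, collapse = ","), sep = ","), con)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV file.
#' @return A [feature_table()]; empty fields become masked NA entries.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  vals <- vapply(df[-1L], function(col) {
    col[!nzchar(col)] <- NA_character_
    as.numeric(col)
  }, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, names(df)[-1L]))
  feature_table(vals, cell_ids = ids, feature_names = colnames(vals))
}
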