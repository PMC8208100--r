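#' Construct a recorded sweep
#'
#' A sweep is a uniformly sampled trace: membrane potential (mV) in current
#' clamp or membrane current (pA) in voltage clamp. Protocol epochs annotate
#' the command waveform (holding and step periods) so that downstream
#' operations can locate stimulus onsets without re-deriving them from data.
#'
#' @param samples Numeric vector of measured values (mV or pA), length >= 2.
#' @param dt Sampling interval in ms. The default 0.1 ms corresponds to
#'   10 kHz acquisition.
#' @param units `"mV"` for current-clamp voltage sweeps, `"pA"` for
#'   voltage-clamp current sweeps.
#' @param epochs Optional data frame of protocol epochs, see [protocol_epochs()].
#' @param meta Optional named list of free-form annotations (e.g. the step
#'   amplitude of this sweep within a family).
#' @return An object of class `"sweep"`.
#' @export
sweep_trace <- function(samples, dt = 0.1, units = c("mV", "pA"),
                        epochs = NULL, meta = list()) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (ms)", call. = FALSE)
  }
  if (length(samples) < 2L) {
    stop("a sweep needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(samples)) stop("sweep samples must not contain NA", call. = FALSE)
  if (!is.null(epochs)) {
    epochs <- validate_epochs(epochs, duration_ms = (length(samples) - 1L) * dt)
  }
  structure(
    list(samples = samples, dt = dt, units = units,
         epochs = epochs, meta = meta),
    class = "sweep"
  )
}

#' Protocol epoch table
#'
#' @param start_ms,duration_ms Epoch timing in ms.
#' @param command_level Command level: pA for current steps, mV for voltage
#'   steps.
#' @param kind `"holding"` or `"step"`.
#' @return A validated data frame with one row per epoch.
#' @export
protocol_epochs <- function(start_ms, duration_ms, command_level, kind) {
  df <- data.frame(start_ms = as.numeric(start_ms),
                   duration_ms = as.numeric(duration_ms),
                   command_level = as.numeric(command_level),
                   kind = as.character(kind),
                   stringsAsFactors = FALSE)
  validate_epochs(df)
}

validate_epochs <- function(epochs, duration_ms = NULL) {
  needed <- c("start_ms", "duration_ms", "command_level", "kind")
  if (!is.data.frame(epochs) || !all(needed %in% names(epochs))) {
    stop("epochs must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  epochs <- epochs[needed]
  if (!all(epochs$kind %in% c("holding", "step"))) {
    stop("epoch kind must be 'holding' or 'step'", call. = FALSE)
  }
  if (any(epochs$duration_ms <= 0) || any(epochs$start_ms < 0)) {
    stop("epochs must have start_ms >= 0 and duration_ms > 0", call. = FALSE)
  }
  o <- order(epochs$start_ms)
  epochs <- epochs[o, , drop = FALSE]
  ends <- epochs$start_ms + epochs$duration_ms
  if (nrow(epochs) > 1L &&
      any(epochs$start_ms[-1L] < ends[-nrow(epochs)] - 1e-9)) {
    stop("epochs overlap", call. = FALSE)
  }
  if (!is.null(duration_ms) && any(ends > duration_ms + 1e-9)) {
    stop("epochs extend beyond the sweep duration", call. = FALSE)
  }
  rownames(epochs) <- NULL
  epochs
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %d samples @ dt = %g ms (%s), %.1f ms\n",
              length(x$samples), x$dt, x$units,
              (length(x$samples) - 1L) * x$dt))
  invisible(x)
}

#' Time axis of a sweep
#'
#' @param sweep A [sweep_trace()] object.
#' @return Numeric vector of sample times in ms, starting at 0.
#' @export
sweep_time <- function(sweep) {
  stopifnot(inherits(sweep, "sweep"))
  (seq_along(sweep$samples) - 1L) * sweep$dt
}

#' Locate the (first) step epoch of a sweep
#' @noRd
step_epoch <- function(sweep) {
  ep <- sweep$epochs
  if (is.null(ep) || !any(ep$kind == "step")) {
    stop("sweep has no annotated step epoch", call. = FALSE)
  }
  ep[ep$kind == "step", , drop = FALSE][1L, ]
}

assert_units <- function(sweep, units, what = "this operation") {
  if (!inherits(sweep, "sweep")) {
    stop("expected a sweep object", call. = FALSE)
  }
  if (sweep$units != units) {
    stop(sprintf("%s requires a %s sweep, got %s; sweeps are never rescaled",
                 what, units, sweep$units), call. = FALSE)
  }
  invisible(sweep)
}

## Protocol groups recognised in a CellRecord. Unknown groups are rejected at
## construction and at bundle read.
PROTOCOL_GROUPS <- c("step_family", "passive_5mV", "passive_60s",
                     "subthreshold_VC", "sepsc_VC", "retest_family")

#' Construct a per-cell record
#'
#' Bundles all sweeps and metadata for one recorded neuron. Sweeps are grouped
#' by protocol: `step_family` (1-s depolarising current steps in 20-pA
#' increments from a -70 mV holding potential), `passive_5mV` (repeated -5 mV
#' seal-test steps, voltage clamp), `passive_60s` (long passive current-clamp
#' recording at 0 pA bias), `subthreshold_VC` (hyperpolarising then -40 mV
#' voltage-step protocol with P/N subsweeps), `sepsc_VC` (continuous voltage
#' clamp at -70 mV), and `retest_family` (current steps repeated from a more
#' depolarised holding potential, used for the reluctant-firing call).
#'
#' @param cell_id Character scalar.
#' @param identity `"SPBN"` (retrogradely labelled projection neuron) or
#'   `"UN"` (unlabelled neuron).
#' @param lamina `"LI"` or `"LIII_V"`.
#' @param slice_plane `"transverse"` or `"sagittal"`.
#' @param sweeps Named list; each element a list of [sweep_trace()] objects
#'   for one protocol group.
#' @param bias_current_pA Standing bias current used to hold -70 mV; must be
#'   within +/- 20 pA.
#' @return An object of class `"cell_record"`.
#' @export
cell_record <- function(cell_id, identity = c("SPBN", "UN"),
                        lamina = c("LI", "LIII_V"),
                        slice_plane = c("transverse", "sagittal"),
                        sweeps = list(), bias_current_pA = 0) {
  identity <- match.arg(identity)
  lamina <- match.arg(lamina)
  slice_plane <- match.arg(slice_plane)
  if (!is.character(cell_id) || length(cell_id) != 1L || !nzchar(cell_id)) {
    stop("`cell_id` must be a non-empty string", call. = FALSE)
  }
  if (abs(bias_current_pA) > 20) {
    stop("bias current must be within +/- 20 pA", call. = FALSE)
  }
  if (length(sweeps)) {
    bad <- setdiff(names(sweeps), PROTOCOL_GROUPS)
    if (length(bad) || is.null(names(sweeps))) {
      stop("unknown protocol group(s): ",
           paste(bad, collapse = ", "),
           "; known groups are ", paste(PROTOCOL_GROUPS, collapse = ", "),
           call. = FALSE)
    }
    for (g in names(sweeps)) {
      grp <- sweeps[[g]]
      if (!length(grp) || !all(vapply(grp, inherits, TRUE, "sweep"))) {
        stop("group '", g, "' must be a non-empty list of sweeps",
             call. = FALSE)
      }
      dts <- vapply(grp, `[[`, 0, "dt")
      us <- vapply(grp, `[[`, "", "units")
      if (length(unique(dts)) != 1L || length(unique(us)) != 1L) {
        stop("group '", g, "' mixes dt or units across sweeps", call. = FALSE)
      }
    }
  }
  structure(
    list(cell_id = cell_id, identity = identity, lamina = lamina,
         slice_plane = slice_plane, sweeps = sweeps,
         bias_current_pA = bias_current_pA),
    class = "cell_record"
  )
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("<cell_record> %s (%s, %s, %s slice)\n",
              x$cell_id, x$identity, x$lamina, x$slice_plane))
  for (g in names(x$sweeps)) {
    cat(sprintf("  %-16s %d sweep(s)\n", g, length(x$sweeps[[g]])))
  }
  invisible(x)
}

#' Construct a feature table
#'
#' One row per cell, one column per continuous electrophysiological feature.
#' Missing entries (features undefined for a cell, e.g. adaptation with fewer
#' than two spikes) are carried in `values` as NA with the positions recorded
#' in `mask` until imputation.
#'
#' @param values Numeric matrix (cells x features).
#' @param cell_ids Character vector of row identifiers (unique).
#' @param feature_names Character vector of column names.
#' @param mask Logical matrix marking missing entries; defaults to
#'   `is.na(values)`.
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(values, cell_ids = rownames(values),
                          feature_names = colnames(values), mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids) || is.null(feature_names)) {
    stop("cell_ids and feature_names are required", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids", call. = FALSE)
  if (length(cell_ids) != nrow(values) ||
      length(feature_names) != ncol(values)) {
    stop("dimension mismatch between values and names", call. = FALSE)
  }
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) {
    stop("mask dimensions must match values", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, feature_names)
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 feature_names = as.character(feature_names), mask = mask),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cells x %d features (%d missing)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}
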