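#' P/N leak subtraction
#'
#' Subtracts the linear (leak plus capacitive) component of a voltage-clamp
#' response using `n` subsweeps recorded with the command step scaled down
#' by `1/n` (P/4 is the default protocol). Each trace is referenced to its
#' own pre-step holding baseline before scaling so that a pure ohmic cell
#' yields a flat zero trace whatever its resting conductance:
#' `corrected = (test - base_test) - n * mean(sub_i - base_sub_i)`.
#'
#' @param test Voltage-clamp current sweep (pA), annotated epochs.
#' @param subsweeps List of current sweeps recorded with 1/n-scaled commands.
#' @param n Scaling factor (> 0); defaults to the number of subsweeps.
#' @return A corrected [sweep_trace()] carrying the test sweep's epochs.
#' @export
pn_leak_subtract <- function(test, subsweeps, n = length(subsweeps)) {
  assert_units(test, "pA", "P/N subtraction")
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("`n` must be a positive scaling factor", call. = FALSE)
  }
  if (!length(subsweeps)) stop("no subsweeps supplied", call. = FALSE)
  len <- length(test$samples)
  ep <- sweep_epochs_or_error(test)
  first_step <- min(ep$start_ms[ep$kind == "step"])
  base_of <- function(sw) {
    tt <- sweep_time(sw)
    mean(sw$samples[tt < first_step])
  }
  sub_mat <- vapply(subsweeps, function(sw) {
    assert_units(sw, "pA", "P/N subtraction")
    if (length(sw$samples) != len || sw$dt != test$dt) {
      stop("protocol error: subsweep length/dt mismatch", call. = FALSE)
    }
    sw$samples - base_of(sw)
  }, numeric(len))
  corrected <- (test$samples - base_of(test)) - n * rowMeans(sub_mat)
  sweep_trace(corrected, dt = test$dt, units = "pA", epochs = test$epochs,
              meta = c(test$meta, list(pn_subtracted = TRUE, pn_n = n)))
}

#' Classify the subthreshold voltage-activated current
#'
#' Operates on the P/N-subtracted response to the depolarising -40 mV step
#' (200 ms). The dominant transient is the extremum of largest magnitude
#' relative to the pre-step baseline. An outward (positive) transient is a
#' fast A-type potassium current when its latency to peak is under 15 ms and
#' a slow one otherwise (a peak at exactly 15.0 ms is classed slow: the fast
#' definition is strictly `< 15 ms`). An inward transient is T-type-like.
#' Peaks below the noise floor (`nc_sd_mult` times the sd of the 50-ms
#' pre-step baseline) are "no current" (NC).
#'
#' @param corrected P/N-subtracted current sweep, epochs annotated; the
#'   -40 mV step is located by its `command_level`.
#' @param step_command_mV Command level of the depolarising step (default -40).
#' @param nc_sd_mult Noise-floor multiplier (default 4).
#' @param blank_ms Initial portion of the step ignored (residual clamp
#'   artifact), default 1 ms.
#' @param smooth_ms Running-mean window applied before peak measurement
#'   (default 2 ms). The currents of interest have multi-millisecond
#'   kinetics, so the smoothing does not bias their peaks but keeps the
#'   noise floor a statement about the trace on which the peak is actually
#'   searched.
#' @return A `"subthreshold_profile"` list: `current_class` (KA_fast,
#'   KA_slow, CaT_like, NC), `peak_amplitude_pA` (signed), `latency_ms`,
#'   `half_decay_ms`, `noise_floor_pA`, `secondary` diagnostics.
#' @export
classify_subthreshold <- function(corrected, step_command_mV = -40,
                                  nc_sd_mult = 4, blank_ms = 1,
                                  smooth_ms = 2) {
  assert_units(corrected, "pA", "subthreshold classification")
  ep <- sweep_epochs_or_error(corrected)
  step <- ep[ep$kind == "step" & ep$command_level == step_command_mV, ,
             drop = FALSE]
  if (!nrow(step)) {
    stop("protocol error: no step epoch at ", step_command_mV, " mV",
         call. = FALSE)
  }
  step <- step[1L, ]
  tt <- sweep_time(corrected)
  raw <- corrected$samples
  k <- max(1L, round(smooth_ms / corrected$dt))
  i_all <- raw
  if (k > 1L) {
    sm <- as.numeric(stats::filter(raw, rep(1 / k, k), sides = 2))
    i_all <- ifelse(is.na(sm), raw, sm)
  }
  pre <- tt >= step$start_ms - 50 & tt < step$start_ms
  if (!any(pre)) stop("protocol error: no 50 ms pre-step baseline",
                      call. = FALSE)
  base <- mean(i_all[pre])
  # baseline sd estimated on the raw trace (many independent samples) and
  # scaled analytically to the smoothed trace on which peaks are searched
  floor_pA <- nc_sd_mult * stats::sd(raw[pre]) / sqrt(k)
  win <- tt >= step$start_ms + blank_ms &
    tt < step$start_ms + step$duration_ms
  y <- i_all[win] - base
  tw <- tt[win] - step$start_ms
  i_max <- which.max(y); i_min <- which.min(y)
  dominant_out <- y[i_max] >= -y[i_min]
  i_pk <- if (dominant_out) i_max else i_min
  peak <- y[i_pk]
  latency <- tw[i_pk]
  secondary <- list(outward_pA = y[i_max], inward_pA = y[i_min])
  if (abs(peak) < floor_pA) {
    cls <- "NC"; peak_out <- NA_real_; latency_out <- NA_real_
    half <- NA_real_
  } else {
    cls <- if (peak > 0) {
      if (latency < 15) "KA_fast" else "KA_slow"
    } else "CaT_like"
    peak_out <- peak; latency_out <- latency
    # 50% decay: first time after the peak at which the magnitude halves
    post <- y[i_pk:length(y)]
    cross <- which(abs(post) <= abs(peak) / 2)
    half <- if (length(cross)) tw[i_pk + cross[1L] - 1L] - latency
            else NA_real_
  }
  structure(list(current_class = cls, peak_amplitude_pA = peak_out,
                 latency_ms = latency_out, half_decay_ms = half,
                 noise_floor_pA = floor_pA, secondary = secondary),
            class = "subthreshold_profile")
}

#' @export
print.subthreshold_profile <- function(x, ...) {
  cat(sprintf("<subthreshold_profile> %s (peak %.1f pA at %.1f ms)\n",
              x$current_class,
              if (is.na(x$peak_amplitude_pA)) 0 else x$peak_amplitude_pA,
              if (is.na(x$latency_ms)) NA else x$latency_ms))
  invisible(x)
}

#' Detect a hyperpolarisation-activated sag current (Ih)
#'
#' During a long hyperpolarising voltage step, Ih appears as a slowly
#' ramping inward current. Amplitude is the difference between the early
#' plateau (20-100 ms after step onset, once the instantaneous ohmic level
#' is established) and the end of the step; the current is called present
#' when that inward development exceeds `sd_mult` times the pre-step baseline
#' sd and develops monotonically (the midpoint lies between the plateau and
#' end levels).
#'
#' @param sweep Current sweep (pA) with a hyperpolarising step epoch of at
#'   least 1 s.
#' @param step_command_mV Command level of the hyperpolarising step; by
#'   default the most negative step epoch is used.
#' @param sd_mult Noise criterion multiplier (default 3).
#' @return List: `present`, `amplitude_pA` (positive = inward development),
#'   `flag` (`"epoch too short"` when undefined).
#' @export
detect_ih <- function(sweep, step_command_mV = NULL, sd_mult = 3) {
  assert_units(sweep, "pA", "Ih detection")
  ep <- sweep_epochs_or_error(sweep)
  steps <- ep[ep$kind == "step", , drop = FALSE]
  if (!nrow(steps)) stop("protocol error: no step epoch", call. = FALSE)
  step <- if (is.null(step_command_mV)) {
    steps[which.min(steps$command_level), ]
  } else {
    steps[steps$command_level == step_command_mV, , drop = FALSE][1L, ]
  }
  if (step$duration_ms < 1000) {
    return(list(present = NA, amplitude_pA = NA_real_,
                flag = "epoch too short"))
  }
  tt <- sweep_time(sweep)
  pre <- tt >= step$start_ms - 50 & tt < step$start_ms
  noise <- stats::sd(sweep$samples[pre])
  early <- mean(sweep$samples[tt >= step$start_ms + 20 &
                                tt < step$start_ms + 100])
  t_end <- step$start_ms + step$duration_ms
  late <- mean(sweep$samples[tt >= t_end - 50 & tt < t_end])
  t_mid <- step$start_ms + (100 + step$duration_ms) / 2
  mid <- mean(sweep$samples[tt >= t_mid - 25 & tt < t_mid + 25])
  amp <- early - late                 # inward (downward) development > 0
  monotone <- (mid <= early + noise) && (mid >= late - noise)
  list(present = amp > sd_mult * noise && monotone,
       amplitude_pA = amp, flag = NULL)
}
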