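#' Detect action potentials by dV/dt criterion
#'
#' Spike threshold is where the centered-difference dV/dt of a rising
#' excursion reaches the criterion (15 mV/ms by default); the spike peak is
#' the subsequent local voltage maximum. When a strong current step charges
#' the membrane faster than the criterion, the passive onset and the first
#' AP upstroke merge into a single rising excursion; the threshold is
#' therefore anchored at the last upward crossing of the criterion before
#' the peak, which for an AP rising out of a subthreshold baseline is the
#' same as the first. After a peak the detector is locked out until the
#' trace falls back below that spike's threshold voltage. dV/dt is computed
#' on the raw, unsmoothed trace: at 10 kHz sampling centered differences
#' are stable without filtering.
#'
#' A rising excursion only counts as an action potential if its peak exceeds
#' `min_peak_mV`: large current steps charge the membrane faster than
#' 15 mV/ms, and without a peak-height floor the passive onset of a strong
#' step would register as a spike.
#'
#' @param sweep Current-clamp [sweep_trace()] (mV); voltage-clamp sweeps are
#'   rejected, never rescaled.
#' @param dvdt_threshold Criterion in mV/ms (default 15).
#' @param min_peak_mV Minimum peak voltage of a genuine spike (default -20).
#' @return A `"spike_train"` data frame: `threshold_time_ms`,
#'   `threshold_mV`, `peak_time_ms`, `peak_mV`; step amplitude (if annotated
#'   in the sweep meta) in the `"step_pA"` attribute.
#' @export
detect_spikes <- function(sweep, dvdt_threshold = 15,
                          min_peak_mV = -20) {
  assert_units(sweep, "mV", "spike detection")
  v <- sweep$samples
  dt <- sweep$dt
  n <- length(v)
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt), NA)
  thr_t <- thr_v <- pk_t <- pk_v <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    if (!is.na(dvdt[i]) && dvdt[i] >= dvdt_threshold) {
      j <- i
      while (j < n && v[j + 1L] >= v[j]) j <- j + 1L
      if (v[j] > min_peak_mV) {
        # re-anchor the threshold at the last upward crossing of the
        # criterion before the peak: when a strong step charges the membrane
        # faster than the criterion, the passive onset and the AP upstroke
        # merge into one rising excursion and the first crossing sits at the
        # holding potential, not at the spike foot. For an AP rising out of
        # a subthreshold baseline the last crossing IS the first one.
        t <- j
        while (t > i && !(dvdt[t] >= dvdt_threshold &&
                          (is.na(dvdt[t - 1L]) ||
                             dvdt[t - 1L] < dvdt_threshold))) t <- t - 1L
        if (t == i || is.na(dvdt[t]) || dvdt[t] < dvdt_threshold) t <- i
        v_thr <- v[t]
        thr_t <- c(thr_t, (t - 1L) * dt); thr_v <- c(thr_v, v_thr)
        pk_t <- c(pk_t, (j - 1L) * dt); pk_v <- c(pk_v, v[j])
        # lockout until the trace falls back below the threshold voltage
        k <- j
        while (k < n && v[k] >= v_thr) k <- k + 1L
        i <- k + 1L
      } else {
        i <- j + 1L   # not a spike: resume past the excursion, no lockout
      }
    } else {
      i <- i + 1L
    }
  }
  out <- data.frame(threshold_time_ms = thr_t, threshold_mV = thr_v,
                    peak_time_ms = pk_t, peak_mV = pk_v)
  class(out) <- c("spike_train", class(out))
  attr(out, "step_pA") <- sweep$meta$step_pA
  out
}

#' Passive membrane properties from seal-test sweeps
#'
#' Averages repeated responses to a small hyperpolarising voltage step
#' (-5 mV, 30 trials in the standard protocol). Input resistance is
#' `|dV / dI_ss|` with the steady-state current taken over the final 20% of
#' the step; membrane capacitance is the charge of the leak-subtracted
#' capacitive transient divided by the step size. Charge integration is
#' robust to series resistance, unlike a single-exponential fit.
#'
#' @param sweeps List of voltage-clamp current sweeps (pA) with an annotated
#'   step epoch whose `command_level` is the absolute command in mV.
#' @return List with `Rin_MOhm`, `Cm_pF`, `n_sweeps`.
#' @export
measure_passive <- function(sweeps) {
  if (!length(sweeps)) stop("no sweeps supplied", call. = FALSE)
  for (sw in sweeps) assert_units(sw, "pA", "passive measurement")
  ep <- sweep_epochs_or_error(sweeps[[1L]])
  step <- ep[ep$kind == "step", , drop = FALSE]
  if (!nrow(step)) stop("protocol error: no step epoch", call. = FALSE)
  step <- step[1L, ]
  hold <- ep[ep$kind == "holding", , drop = FALSE]
  if (!nrow(hold)) stop("protocol error: no holding epoch", call. = FALSE)
  dv <- step$command_level - hold$command_level[1L]
  if (dv == 0) stop("protocol error: zero step amplitude", call. = FALSE)
  dt <- sweeps[[1L]]$dt
  avg <- rowMeans(vapply(sweeps, `[[`,
                         numeric(length(sweeps[[1L]]$samples)), "samples"))
  tt <- (seq_along(avg) - 1L) * dt
  pre <- avg[tt < step$start_ms]
  if (!length(pre)) stop("protocol error: no pre-step baseline", call. = FALSE)
  i_base <- mean(pre)
  t_end <- step$start_ms + step$duration_ms
  ss_win <- tt >= (t_end - 0.2 * step$duration_ms) & tt < t_end
  i_ss <- mean(avg[ss_win])
  di <- i_ss - i_base                        # pA
  rin <- abs(dv / di) * 1000                 # mV / pA -> MOhm
  # capacitive transient: the access-resistance-limited transient lasts
  # tens of microseconds to ~1 ms, so a 5-ms window (capped at a quarter of
  # the step) captures it completely while keeping the integrated baseline
  # noise small; leak line = steady-state plateau
  tr_len <- min(5, 0.25 * step$duration_ms)
  tr_win <- tt >= step$start_ms & tt < (step$start_ms + tr_len)
  q <- sum(avg[tr_win] - i_ss) * dt          # pA ms = fC
  cm <- abs(q / dv)                          # fC / mV = pF
  list(Rin_MOhm = rin, Cm_pF = cm, n_sweeps = length(sweeps))
}

sweep_epochs_or_error <- function(sweep) {
  if (is.null(sweep$epochs)) {
    stop("protocol error: sweep has no epoch annotation", call. = FALSE)
  }
  sweep$epochs
}

#' Resting membrane potential from a passive recording
#'
#' Mean of the spike-free samples of a long current-clamp recording at 0 pA
#' bias; windows of +/- 5 ms around detected spikes are excluded. Recordings
#' shorter than 30 s are used in full with a warning.
#'
#' @param sweep Current-clamp sweep (mV).
#' @param spikes Optional precomputed [detect_spikes()] result.
#' @return RMP in mV.
#' @export
measure_rmp <- function(sweep, spikes = detect_spikes(sweep)) {
  assert_units(sweep, "mV", "RMP measurement")
  dur_s <- (length(sweep$samples) - 1L) * sweep$dt / 1000
  if (dur_s < 30) {
    warning(sprintf("recording is %.1f s (< 30 s); RMP computed on available length",
                    dur_s), call. = FALSE)
  }
  keep <- rep(TRUE, length(sweep$samples))
  tt <- sweep_time(sweep)
  for (tp in spikes$peak_time_ms) {
    keep[tt >= tp - 5 & tt <= tp + 5] <- FALSE
  }
  mean(sweep$samples[keep])
}

#' Classify spontaneous activity from a passive recording
#'
#' `none` with no spikes; `bursting` when at least two clusters of >= 3
#' spikes with intra-burst intervals < 100 ms are separated by silences
#' > 1 s; `tonic` when the interspike-interval coefficient of variation is
#' below 0.5; otherwise `irregular`. The burst rule is checked before the
#' CV rule since it is the more specific structure.
#'
#' @param spike_times_ms Spike times in ms over the recording.
#' @return One of `"none"`, `"irregular"`, `"tonic"`, `"bursting"`.
#' @export
classify_spontaneous <- function(spike_times_ms) {
  st <- sort(spike_times_ms)
  if (length(st) == 0L) return("none")
  if (length(st) == 1L) return("irregular")
  isi <- diff(st)
  # burst structure: split at silences > 1 s
  grp <- cumsum(c(0, isi > 1000))
  burst_like <- vapply(split(st, grp), function(b) {
    length(b) >= 3L && all(diff(b) < 100)
  }, TRUE)
  if (sum(burst_like) >= 2L) return("bursting")
  cv <- stats::sd(isi) / mean(isi)
  if (cv < 0.5) "tonic" else "irregular"
}

#' Rheobase from a current-step family
#'
#' The smallest step amplitude whose response contains at least one action
#' potential. A family with no spiking anywhere is flagged as a
#' reluctant-firing candidate rather than an error.
#'
#' @param sweeps List of current-clamp sweeps with `meta$step_pA` set.
#' @param dvdt_threshold Spike criterion, see [detect_spikes()].
#' @return List: `rheobase_pA`, `index` (into the amplitude-ordered family),
#'   `reluctant_candidate`, `boundary_warning`, `spike_trains` (per sweep,
#'   amplitude order), `order`.
#' @export
find_rheobase <- function(sweeps, dvdt_threshold = 15) {
  amps <- vapply(sweeps, function(s) {
    a <- s$meta$step_pA
    if (is.null(a)) stop("sweep lacks meta$step_pA", call. = FALSE)
    as.numeric(a)
  }, 1)
  o <- order(amps)
  sweeps <- sweeps[o]; amps <- amps[o]
  trains <- lapply(sweeps, detect_spikes, dvdt_threshold = dvdt_threshold)
  n_sp <- vapply(trains, nrow, 1L)
  idx <- which(n_sp >= 1L)
  if (!length(idx)) {
    return(list(rheobase_pA = NA_real_, index = NA_integer_,
                reluctant_candidate = TRUE, boundary_warning = FALSE,
                spike_trains = trains, order = o))
  }
  first <- min(idx)
  boundary <- first == 1L
  if (boundary) {
    warning("spikes already at the smallest step; rheobase is an upper bound",
            call. = FALSE)
  }
  list(rheobase_pA = amps[first], index = first,
       reluctant_candidate = FALSE, boundary_warning = boundary,
       spike_trains = trains, order = o)
}

#' Discharge metrics of a step response
#'
#' Computed on the evaluation sweep (rheobase + 40 pA, i.e. two 20-pA steps
#' above rheobase). Latency is step onset to first spike threshold;
#' interspike intervals run between successive peaks; adaptation is the last
#' instantaneous frequency over the first; attenuation the last spike's peak
#' amplitude (peak minus its threshold) over the first, reported as a
#' percentage. With fewer than two spikes the train-based metrics are
#' undefined (`NA`, `defined = FALSE`).
#'
#' @param spikes A [detect_spikes()] train.
#' @param step_start_ms,step_duration_ms Step epoch timing.
#' @return List of metrics (see `default_feature_panel()` naming).
#' @export
discharge_metrics <- function(spikes, step_start_ms, step_duration_ms) {
  n <- nrow(spikes)
  out <- list(first_spike_latency_ms = NA_real_, isis_ms = numeric(0),
              instantaneous_freqs_Hz = numeric(0),
              mean_frequency_Hz = NA_real_,
              mean_instantaneous_frequency_Hz = NA_real_,
              discharge_duration_ms = NA_real_,
              adaptation = NA_real_, attenuation_pct = NA_real_,
              n_spikes = n, defined = FALSE)
  if (n == 0L) return(out)
  out$first_spike_latency_ms <- spikes$threshold_time_ms[1L] - step_start_ms
  out$mean_frequency_Hz <- n / (step_duration_ms / 1000)
  if (n < 2L) return(out)
  isis <- diff(spikes$peak_time_ms)
  freqs <- 1000 / isis
  amps <- spikes$peak_mV - spikes$threshold_mV
  out$isis_ms <- isis
  out$instantaneous_freqs_Hz <- freqs
  out$mean_instantaneous_frequency_Hz <- mean(freqs)
  out$discharge_duration_ms <-
    spikes$peak_time_ms[n] - spikes$peak_time_ms[1L]
  out$adaptation <- freqs[length(freqs)] / freqs[1L]
  out$attenuation_pct <- 100 * amps[n] / amps[1L]
  out$defined <- TRUE
  out
}

#' Action potential waveform features
#'
#' Measured on one spike (by convention the first spike of the
#' rheobase + 40 pA response), with the threshold voltage taken from the
#' rheobase response. All six features follow the standard definitions:
#' peak amplitude is peak minus threshold; rise time runs from the upward
#' threshold crossing to the peak; base width is the width at the threshold
#' voltage; AHP amplitude is trough minus threshold (negative by
#' convention); AHP latency is threshold crossing to trough. The trough is
#' searched between the spike and the next spike (or sweep end), capped at
#' 200 ms after threshold to avoid step-offset artifacts.
#'
#' @param sweep Current-clamp sweep containing the spike.
#' @param spikes [detect_spikes()] train for `sweep`.
#' @param spike_index Which spike to measure (default 1).
#' @param threshold_mV Threshold voltage; defaults to the measured threshold
#'   of the chosen spike (pass the rheobase-sweep value to follow the
#'   standard convention).
#' @return List: `threshold_mV`, `peak_amplitude_mV`, `rise_ms`,
#'   `base_width_ms`, `ahp_amplitude_mV`, `ahp_latency_ms`, `ahp_defined`.
#' @export
ap_waveform_features <- function(sweep, spikes = detect_spikes(sweep),
                                 spike_index = 1L, threshold_mV = NULL) {
  assert_units(sweep, "mV", "AP waveform analysis")
  if (nrow(spikes) < spike_index) {
    stop("requested spike not present in the train", call. = FALSE)
  }
  v <- sweep$samples; dt <- sweep$dt; tt <- sweep_time(sweep)
  sp <- spikes[spike_index, ]
  thr <- if (is.null(threshold_mV)) sp$threshold_mV else threshold_mV
  i_pk <- round(sp$peak_time_ms / dt) + 1L
  # upward crossing of thr before the peak
  i0 <- i_pk
  while (i0 > 1L && v[i0 - 1L] >= thr) i0 <- i0 - 1L
  t_up <- interp_crossing(tt, v, i0 - 1L, thr, rising = TRUE)
  # downward crossing after the peak
  i1 <- i_pk
  while (i1 < length(v) && v[i1 + 1L] >= thr) i1 <- i1 + 1L
  if (i1 >= length(v)) {
    t_down <- NA_real_
  } else {
    t_down <- interp_crossing(tt, v, i1, thr, rising = FALSE)
  }
  # trough window: end of spike to next spike threshold / 200 ms cap / end
  t_next <- if (nrow(spikes) > spike_index)
    spikes$threshold_time_ms[spike_index + 1L] else tt[length(tt)]
  t_cap <- min(t_next, t_up + 200, tt[length(tt)])
  ahp_amp <- ahp_lat <- NA_real_
  ahp_def <- FALSE
  if (!is.na(t_down) && t_cap > t_down) {
    win <- tt > t_down & tt <= t_cap
    if (any(win)) {
      i_tr <- which(win)[which.min(v[win])]
      ahp_amp <- v[i_tr] - thr
      ahp_lat <- tt[i_tr] - t_up
      ahp_def <- ahp_amp < 0
      if (!ahp_def) { ahp_amp <- NA_real_; ahp_lat <- NA_real_ }
    }
  }
  list(threshold_mV = thr,
       peak_amplitude_mV = sp$peak_mV - thr,
       rise_ms = sp$peak_time_ms - t_up,
       base_width_ms = if (is.na(t_down)) NA_real_ else t_down - t_up,
       ahp_amplitude_mV = ahp_amp,
       ahp_latency_ms = ahp_lat,
       ahp_defined = ahp_def,
       t_threshold_up_ms = t_up,
       t_threshold_down_ms = t_down)
}

## linear interpolation of a level crossing between samples i and i+1
interp_crossing <- function(tt, v, i, level, rising = TRUE) {
  if (i < 1L) return(tt[1L])
  v0 <- v[i]; v1 <- v[i + 1L]
  if (v1 == v0) return(tt[i + 1L])
  frac <- (level - v0) / (v1 - v0)
  frac <- min(max(frac, 0), 1)
  tt[i] + frac * (tt[i + 1L] - tt[i])
}
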