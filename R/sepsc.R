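#' Synaptic event template (difference of exponentials)
#'
#' Inward-going unit template used by the sliding-template detector,
#' normalised to a peak of -1.
#'
#' @param rise_tau_ms,decay_tau_ms Kinetics (decay > rise > 0).
#' @param dt Sampling interval in ms.
#' @param length_ms Template duration; default spans the rise and three
#'   decay time constants -- long enough to capture the event shape while
#'   keeping the detector's dead time (half the template) short enough to
#'   resolve closely spaced events.
#' @return Numeric vector of template samples.
#' @export
epsc_template <- function(rise_tau_ms = 0.5, decay_tau_ms = 4, dt = 0.1,
                          length_ms = rise_tau_ms + 3 * decay_tau_ms) {
  if (!(decay_tau_ms > rise_tau_ms && rise_tau_ms > 0)) {
    stop("need decay_tau > rise_tau > 0", call. = FALSE)
  }
  t <- seq(0, length_ms, by = dt)
  shape <- exp(-t / decay_tau_ms) - exp(-t / rise_tau_ms)
  -shape / max(abs(shape))
}

#' Sliding-template detection of spontaneous EPSCs
#'
#' At every offset the template is optimally scaled and offset by least
#' squares against the trace; the detection statistic is the fitted scale
#' divided by its standard error. Events are local maxima of the statistic
#' above `threshold`, separated by a dead time of half the template length,
#' and must additionally carry a fitted amplitude of at least
#' `min_amplitude_pA` -- the amplitude floor that practical sliding-template
#' implementations apply so that statistically sharp but physically
#' negligible fluctuations are not reported.
#' The offset term makes detection invariant to any DC shift of the sweep.
#' A polarity check -- the trace at the template-peak lag must sit below the
#' onset level by at least the amplitude floor -- rejects outward
#' deflections, whose flanks can otherwise correlate with the template.
#'
#' @param sweep Voltage-clamp current sweep (pA), typically >= 30 s at a
#'   -70 mV holding potential.
#' @param rise_tau_ms,decay_tau_ms Template kinetics (see [epsc_template()]).
#' @param threshold Detection criterion (default 4.5).
#' @param min_amplitude_pA Minimum fitted event amplitude (default 2 pA).
#' @return List: `onset_times_ms`, `criterion` (the statistic trace),
#'   `template`.
#' @export
sliding_template_detect <- function(sweep, rise_tau_ms = 0.5,
                                    decay_tau_ms = 4, threshold = 4.5,
                                    min_amplitude_pA = 2) {
  assert_units(sweep, "pA", "sEPSC detection")
  y <- sweep$samples
  tpl <- epsc_template(rise_tau_ms, decay_tau_ms, dt = sweep$dt)
  N <- length(tpl)
  if (N >= length(y)) stop("template longer than the sweep", call. = FALSE)
  sum_t <- sum(tpl); sum_t2 <- sum(tpl^2)
  denom <- sum_t2 - sum_t^2 / N
  # sliding sums over windows of length N starting at each offset
  cy <- c(0, cumsum(y)); cy2 <- c(0, cumsum(y^2))
  n_off <- length(y) - N + 1L
  sum_y <- cy[(N + 1):(length(y) + 1L)] - cy[1:n_off]
  sum_y2 <- cy2[(N + 1):(length(y) + 1L)] - cy2[1:n_off]
  # sum_ty[k] = sum_j tpl[j] * y[k + j - 1]: FIR filter with reversed template
  f <- stats::filter(y, rev(tpl), method = "convolution", sides = 1)
  sum_ty <- as.numeric(f[N:length(y)])
  scale <- (sum_ty - sum_t * sum_y / N) / denom
  offset <- (sum_y - scale * sum_t) / N
  sse <- sum_y2 + scale^2 * sum_t2 + N * offset^2 -
    2 * (scale * sum_ty + offset * sum_y - scale * offset * sum_t)
  sse[sse < 0] <- 0
  se <- sqrt(sse / (N - 1) / denom)
  crit <- scale / se
  crit[!is.finite(crit)] <- 0
  # candidate events: local maxima of the criterion above threshold
  dead <- floor(N / 2)
  ip <- which.min(tpl) - 1L                 # template peak lag (samples)
  pk_drop <- c(y[(1L + ip):length(y)], rep(Inf, ip)) - y
  nc <- length(crit)
  is_max <- crit > threshold
  is_max[2:(nc - 1)] <- is_max[2:(nc - 1)] &
    crit[2:(nc - 1)] >= crit[1:(nc - 2)] &
    crit[2:(nc - 1)] >= crit[3:nc]
  is_max[c(1L, nc)] <- FALSE
  cand <- which(is_max)
  # each candidate must carry a real inward deflection of at least the
  # amplitude floor, both in the fit and in the raw trace
  cand <- cand[scale[cand] >= min_amplitude_pA &
                 pk_drop[cand] <= -min_amplitude_pA]
  # non-maximum suppression: within a dead time of N/2 only the strongest
  # candidate survives; within a full template length a candidate is also
  # discarded when a neighbour is more than twice as strong -- the weak
  # secondary maximum a matched filter produces when it refits the decay
  # of an event it has already found
  keep <- rep(TRUE, length(cand))
  if (length(cand) > 1L) {
    for (a in seq_along(cand)) {
      for (b in seq_along(cand)) {
        if (a == b || !keep[a]) next
        gap <- abs(cand[a] - cand[b])
        if ((gap < dead && crit[cand[b]] > crit[cand[a]]) ||
            (gap < N && crit[cand[b]] > 2 * crit[cand[a]])) {
          keep[a] <- FALSE
        }
      }
    }
  }
  onsets <- cand[keep]
  list(onset_times_ms = (onsets - 1L) * sweep$dt,
       criterion = crit, template = tpl)
}

#' Event statistics from detected sEPSCs
#'
#' Events are aligned on onset and averaged; amplitude, 10-90% rise time,
#' decay time constant (single-exponential least squares over the 10-90%
#' span of the decay phase), and charge (area between the averaged event
#' and its baseline) are measured on the average. The baseline is the mean
#' of the 2 ms preceding onset. Excitatory drive is charge times frequency,
#' an identity that holds by construction.
#'
#' @param onset_times_ms Detected event onsets.
#' @param sweep The recording the events came from.
#' @param pre_ms,post_ms Averaging window around each onset.
#' @return An `"event_stats"` list: `frequency_Hz`, `mean_amplitude_pA`
#'   (signed, negative = inward), `rise_10_90_ms`, `decay_tau_ms`,
#'   `charge_pA_ms` (magnitude), `drive_pA_ms_Hz`, `n_events`,
#'   `recording_duration_s`, `average` (the averaged event).
#' @export
event_statistics <- function(onset_times_ms, sweep, pre_ms = 2,
                             post_ms = 40) {
  assert_units(sweep, "pA", "sEPSC statistics")
  dt <- sweep$dt
  dur_s <- (length(sweep$samples) - 1L) * dt / 1000
  n_ev <- length(onset_times_ms)
  if (n_ev == 0L) {
    return(structure(list(frequency_Hz = 0, mean_amplitude_pA = NA_real_,
                          rise_10_90_ms = NA_real_, decay_tau_ms = NA_real_,
                          charge_pA_ms = NA_real_, drive_pA_ms_Hz = NA_real_,
                          n_events = 0L, recording_duration_s = dur_s,
                          average = NULL),
                     class = "event_stats"))
  }
  n_pre <- round(pre_ms / dt); n_post <- round(post_ms / dt)
  segs <- sapply(onset_times_ms, function(t0) {
    i0 <- round(t0 / dt) + 1L
    idx <- (i0 - n_pre):(i0 + n_post)
    out <- rep(NA_real_, length(idx))
    ok <- idx >= 1L & idx <= length(sweep$samples)
    out[ok] <- sweep$samples[idx[ok]]
    out
  })
  avg <- rowMeans(segs, na.rm = TRUE)
  t_rel <- (seq_along(avg) - 1L - n_pre) * dt
  base <- mean(avg[t_rel < 0])
  dev <- avg - base
  i_pk <- n_pre + which.min(dev[t_rel >= 0])   # inward peak
  amp <- dev[i_pk]                              # negative pA
  # 10-90% rise (interpolated crossings of |dev| before the peak)
  lev10 <- 0.1 * amp; lev90 <- 0.9 * amp
  rise <- tryCatch({
    seg <- dev[(n_pre + 1L):i_pk]
    ts <- t_rel[(n_pre + 1L):i_pk]
    t10 <- ts[which(seg <= lev10)[1L]]
    t90 <- ts[which(seg <= lev90)[1L]]
    t90 - t10
  }, error = function(e) NA_real_)
  # decay tau: log-linear fit over the 10-90% decay span
  post <- dev[i_pk:length(dev)]
  tpost <- t_rel[i_pk:length(dev)]
  i10 <- which(post >= lev10)[1L]   # decayed to 10% of peak
  i90 <- which(post >= lev90)[1L]   # decayed to 90% remaining
  tau <- NA_real_
  if (!is.na(i10) && !is.na(i90) && i10 > i90 + 2L) {
    span <- i90:i10
    yy <- post[span] / amp           # positive fractions
    ok <- yy > 0
    if (sum(ok) > 2L) {
      fit <- stats::lm(log(yy[ok]) ~ tpost[span][ok])
      tau <- -1 / unname(stats::coef(fit)[2L])
    }
  }
  charge <- abs(sum(dev[t_rel >= 0]) * dt)     # pA ms
  freq <- n_ev / dur_s
  structure(list(frequency_Hz = freq, mean_amplitude_pA = amp,
                 rise_10_90_ms = rise, decay_tau_ms = tau,
                 charge_pA_ms = charge, drive_pA_ms_Hz = charge * freq,
                 n_events = n_ev, recording_duration_s = dur_s,
                 average = avg),
            class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  cat(sprintf(paste0("<event_stats> %d events, %.2f Hz, amp %.1f pA, ",
                     "rise %.2f ms, tau %.2f ms, charge %.0f pA ms\n"),
              x$n_events, x$frequency_Hz, x$mean_amplitude_pA,
              x$rise_10_90_ms, x$decay_tau_ms, x$charge_pA_ms))
  invisible(x)
}
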