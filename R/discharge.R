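#' Operational thresholds for the discharge-pattern rules
#'
#' The field's discharge taxonomy is qualitative; these constants
#' operationalise it. All are surfaced here so a study can tighten or relax
#' them.
#'
#' @param df_min_latency_ms Delayed firing: minimum first-spike latency.
#' @param gf_max_onset_ms Gap firing: the onset spike must occur within this
#'   window.
#' @param gf_gap_ratio Gap firing: first ISI must exceed this multiple of the
#'   median of subsequent ISIs.
#' @param ib_window_ms Initial bursting: onset window containing the burst.
#' @param ib_max_isi_ms Initial bursting: mean intra-burst ISI bound.
#' @param ib_silent_fraction Initial bursting: final fraction of the step that
#'   must be spike-free.
#' @param tf_min_duration_fraction Tonic firing: minimum discharge duration as
#'   a fraction of the step.
#' @param p_gap_ratio Phasic: silent gaps exceed this multiple of the median
#'   ISI.
#' @param rf_headroom_mV Reluctant firing: required depolarisation above the
#'   reference AP threshold.
#' @param rf_reference_threshold_mV Sample-median AP threshold used when the
#'   cell itself never fires.
#' @return Named list of constants.
#' @export
discharge_rules <- function(df_min_latency_ms = 100,
                            gf_max_onset_ms = 50,
                            gf_gap_ratio = 3,
                            ib_window_ms = 100,
                            ib_max_isi_ms = 40,
                            ib_silent_fraction = 0.5,
                            tf_min_duration_fraction = 0.8,
                            p_gap_ratio = 3,
                            rf_headroom_mV = 20,
                            rf_reference_threshold_mV = -40) {
  as.list(environment())
}

#' Classify the discharge pattern of a step-family response
#'
#' Applies the rule set of [discharge_rules()] to the evaluation sweep
#' (rheobase + 40 pA, i.e. two 20-pA increments above the first spiking
#' step), in fixed precedence RF, SS, GF, IB, P, DF, TF -- most specific
#' definitions first. Reluctant firing additionally requires that the step
#' protocol repeated from a more depolarised holding potential does fire.
#' The classifier is deterministic: the same sweeps always give the same
#' call.
#'
#' @param sweeps Step-family current-clamp sweeps with `meta$step_pA`.
#' @param rheo Optional precomputed [find_rheobase()] result.
#' @param retest_sweeps Optional current-step sweeps recorded from a more
#'   depolarised holding potential (needed only for the RF call).
#' @param rules Constants from [discharge_rules()].
#' @param dvdt_threshold Spike criterion.
#' @return A `"discharge_call"` list: `pattern` (one of TF, DF, GF, IB, SS,
#'   P, RF) and `evidence`, the per-rule diagnostics.
#' @export
classify_discharge <- function(sweeps, rheo = NULL, retest_sweeps = NULL,
                               rules = discharge_rules(),
                               dvdt_threshold = 15) {
  if (is.null(rheo)) rheo <- find_rheobase(sweeps, dvdt_threshold)
  sweeps <- sweeps[rheo$order]
  trains <- rheo$spike_trains
  ev <- list()

  if (rheo$reluctant_candidate) {
    # depolarisation actually delivered: plateau of the largest step
    top <- sweeps[[length(sweeps)]]
    step <- step_epoch(top)
    tt <- sweep_time(top)
    late <- tt >= step$start_ms + 0.8 * step$duration_ms &
      tt < step$start_ms + step$duration_ms
    plateau <- mean(top$samples[late])
    ev$max_plateau_mV <- plateau
    ev$depolarised_past_threshold <-
      plateau >= rules$rf_reference_threshold_mV + rules$rf_headroom_mV * 0.75
    retest_fired <- FALSE
    if (!is.null(retest_sweeps)) {
      retest_fired <- any(vapply(retest_sweeps, function(s)
        nrow(detect_spikes(s, dvdt_threshold)) > 0L, TRUE))
    }
    ev$retest_fired <- retest_fired
    if (retest_fired) {
      return(discharge_call("RF", ev))
    }
    stop("unclassifiable: no discharge in the step family and no firing ",
         "depolarised-holding retest", call. = FALSE)
  }

  eval_idx <- rheo$index + 2L
  if (eval_idx > length(sweeps)) {
    stop("protocol error: rheobase + 40 pA sweep missing from the family",
         call. = FALSE)
  }
  sw <- sweeps[[eval_idx]]
  st <- trains[[eval_idx]]
  step <- step_epoch(sw)
  t_on <- step$start_ms; dur <- step$duration_ms
  n <- nrow(st)
  thr_t <- st$threshold_time_ms - t_on
  pk_t <- st$peak_time_ms - t_on
  isis <- if (n >= 2L) diff(st$peak_time_ms) else numeric(0)
  ev$n_spikes <- n
  ev$first_latency_ms <- if (n) thr_t[1L] else NA_real_

  # SS: single spike at onset regardless of step amplitude
  supra <- seq(rheo$index, length(sweeps))
  max_supra <- max(vapply(trains[supra], nrow, 1L))
  ev$max_spikes_suprathreshold <- max_supra
  if (n == 1L && max_supra <= 1L) {
    return(discharge_call("SS", ev))
  }

  # GF: onset spike, long first interval, discharge resumes
  if (n >= 3L) {
    later <- isis[-1L]
    ev$first_isi_ratio <- isis[1L] / stats::median(later)
    if (thr_t[1L] <= rules$gf_max_onset_ms &&
        ev$first_isi_ratio > rules$gf_gap_ratio) {
      return(discharge_call("GF", ev))
    }
  }

  # IB: onset burst, then silence over the late step
  onset <- pk_t <= rules$ib_window_ms
  if (sum(onset) >= 2L) {
    burst_isi <- diff(pk_t[onset])
    ev$onset_burst_isi_ms <- mean(burst_isi)
    late_silent <- !any(pk_t > (1 - rules$ib_silent_fraction) * dur)
    ev$late_silent <- late_silent
    if (mean(burst_isi) < rules$ib_max_isi_ms && late_silent) {
      return(discharge_call("IB", ev))
    }
  }

  # P: >= 2 discharge episodes separated by long silent gaps (an onset
  # single-spike episode alone is GF geometry, not phasic)
  if (n >= 3L) {
    med <- stats::median(isis)
    gap <- isis > rules$p_gap_ratio * med
    epi <- split(seq_len(n), cumsum(c(0, gap)))
    if (length(epi) > 1L && length(epi[[1L]]) == 1L) epi <- epi[-1L]
    ev$n_episodes <- length(epi)
    if (length(epi) >= 2L) {
      return(discharge_call("P", ev))
    }
  }

  # DF: long-latency onset after a depolarising ramp
  if (n >= 1L && thr_t[1L] > rules$df_min_latency_ms) {
    tt <- sweep_time(sw)
    v_early <- mean(sw$samples[tt >= t_on + 20 & tt <= t_on + 40])
    v_pre <- sw$samples[max(which(tt <= t_on + thr_t[1L] - 2))]
    ev$pre_spike_ramp_mV <- v_pre - v_early
    if (ev$pre_spike_ramp_mV > 0) {
      return(discharge_call("DF", ev))
    }
  }

  # TF: sustained discharge across the step
  if (n >= 2L) {
    ev$duration_fraction <- (pk_t[n] - pk_t[1L]) / dur
    if (ev$duration_fraction >= rules$tf_min_duration_fraction) {
      return(discharge_call("TF", ev))
    }
  }

  # residual: repetitive but not sustained/structured -> closest is TF;
  # an isolated evaluation-sweep spike with multi-spike steps elsewhere -> SS
  ev$fallback <- TRUE
  discharge_call(if (n <= 1L) "SS" else "TF", ev)
}

discharge_call <- function(pattern, evidence) {
  structure(list(pattern = pattern, evidence = evidence),
            class = "discharge_call")
}

#' @export
print.discharge_call <- function(x, ...) {
  cat(sprintf("<discharge_call> %s\n", x$pattern))
  str(x$evidence, give.attr = FALSE)
  invisible(x)
}

#' Classify the afterhyperpolarisation profile of a spike
#'
#' Three profiles: `ADP` when a local depolarising maximum (an
#' afterdepolarisation) appears between the end of fast repolarisation and
#' the AHP trough; `slowed` when the falling phase is monotone but carries a
#' pronounced shoulder (the repolarisation rate collapses and then recovers,
#' a second inflection) without any local maximum; otherwise `monophasic`.
#' When an ADP rides on a developing slow hyperpolarisation (post-bump
#' trough deeper than the pre-bump minimum) an `on_slow_ahp` evidence flag
#' is set.
#'
#' @param sweep Current-clamp sweep.
#' @param spikes [detect_spikes()] train; the first spike is analysed by
#'   default.
#' @param spike_index Spike to analyse.
#' @param min_window_ms Required post-peak window (to the next spike or
#'   sweep end); shorter windows return `NA` with a `truncated` flag.
#' @param adp_min_prominence_mV Minimum prominence of an ADP bump.
#' @param shoulder_ratio Slowed-repolarisation criterion: mid-fall slope
#'   magnitude below this fraction of the initial fall slope.
#' @return List: `profile` (`"monophasic"`, `"ADP"`, `"slowed"` or `NA`),
#'   `evidence`.
#' @export
classify_ahp_profile <- function(sweep, spikes = detect_spikes(sweep),
                                 spike_index = 1L, min_window_ms = 50,
                                 adp_min_prominence_mV = 0.5,
                                 shoulder_ratio = 0.25) {
  assert_units(sweep, "mV", "AHP profile analysis")
  v <- sweep$samples; dt <- sweep$dt; tt <- sweep_time(sweep)
  sp <- spikes[spike_index, ]
  t_next <- if (nrow(spikes) > spike_index)
    spikes$threshold_time_ms[spike_index + 1L] else tt[length(tt)]
  if (t_next - sp$peak_time_ms < min_window_ms) {
    return(list(profile = NA_character_,
                evidence = list(truncated = TRUE)))
  }
  win <- tt > sp$peak_time_ms & tt < min(t_next, sp$peak_time_ms + 200)
  idx <- which(win)
  vw <- v[idx]
  i_tr <- which.min(vw)
  ev <- list(truncated = FALSE)

  # search for a depolarising local maximum after fast repolarisation ends
  # (first drop below threshold): the afterdepolarisation may precede the
  # deepest trough (when riding a slow hyperpolarisation) or follow it
  # (classic fast-AHP-then-ADP geometry)
  below <- which(vw < sp$threshold_mV)
  i_start <- if (length(below)) below[1L] else 1L
  seg <- vw[i_start:length(vw)]
  if (length(seg) >= 5L) {
    # local maxima with prominence
    loc_max <- which(diff(sign(diff(seg))) == -2) + 1L
    for (m in loc_max) {
      left_min <- min(seg[1:m])
      right_min <- min(seg[m:length(seg)])
      prom <- seg[m] - max(left_min, right_min)
      if (prom >= adp_min_prominence_mV) {
        ev$adp_prominence_mV <- prom
        pre_min <- left_min
        post_min <- right_min
        ev$on_slow_ahp <- post_min < pre_min
        return(list(profile = "ADP", evidence = ev))
      }
    }
  }

  # slowed repolarisation: shoulder in the falling phase between peak and
  # the first threshold crossing region
  fall_end <- i_start
  if (fall_end >= 6L) {
    slope <- diff(vw[1:fall_end]) / dt
    k <- max(2L, ceiling(0.5 / dt))           # smooth over ~0.5 ms
    sm <- stats::filter(slope, rep(1 / k, k), sides = 2)
    sm <- sm[!is.na(sm)]
    if (length(sm) >= 5L) {
      init <- min(sm[1:max(2L, ceiling(length(sm) / 4))])  # steepest early fall
      interior <- sm[-c(1:2, (length(sm) - 1):length(sm))]
      # slopes are negative during the fall; a shoulder drives the interior
      # slope toward zero while the trace keeps falling (no local maximum)
      ev$min_fall_ratio <- max(interior) / init
      if (all(sm < 0.5) && ev$min_fall_ratio < shoulder_ratio) {
        return(list(profile = "slowed", evidence = ev))
      }
    }
  }
  list(profile = "monophasic", evidence = ev)
}

#' Detect an initial depolarising hump at rheobase
#'
#' Works on the spike-clipped subthreshold envelope of the rheobase sweep:
#' spikes are excised (threshold crossing to return below threshold) and the
#' envelope linearly interpolated across them, then smoothed with a 5-ms
#' running mean. A hump is an early envelope maximum at least
#' `min_hump_mV` above the late-step plateau (mean over the final 20%),
#' occurring in the first half of the step.
#'
#' @param sweep Rheobase current-clamp sweep with a step epoch.
#' @param spikes Optional precomputed spike train.
#' @param min_hump_mV Required elevation above the plateau (default 2 mV).
#' @return Logical.
#' @export
detect_depolarizing_hump <- function(sweep, spikes = detect_spikes(sweep),
                                     min_hump_mV = 2) {
  assert_units(sweep, "mV", "hump detection")
  step <- step_epoch(sweep)
  v <- sweep$samples; tt <- sweep_time(sweep); dt <- sweep$dt
  # excise spikes
  keep <- rep(TRUE, length(v))
  for (i in seq_len(nrow(spikes))) {
    t0 <- spikes$threshold_time_ms[i]
    j <- round(spikes$peak_time_ms[i] / dt) + 1L
    while (j < length(v) && v[j] >= spikes$threshold_mV[i]) j <- j + 1L
    keep[tt >= t0 - 1 & tt <= tt[j] + 1] <- FALSE
  }
  env <- v
  if (any(!keep)) {
    env[!keep] <- stats::approx(tt[keep], v[keep], xout = tt[!keep],
                                rule = 2)$y
  }
  k <- max(1L, round(5 / dt))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  t_end <- step$start_ms + step$duration_ms
  in_step <- tt >= step$start_ms & tt < t_end & !is.na(env)
  early <- in_step & tt < step$start_ms + 0.5 * step$duration_ms
  late <- in_step & tt >= t_end - 0.2 * step$duration_ms
  if (!any(early) || !any(late)) return(FALSE)
  max(env[early]) >= mean(env[late]) + min_hump_mV
}
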