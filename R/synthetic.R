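#' Phenotype specification for the synthetic neuron
#'
#' Describes one model cell: passive properties, spike mechanism, and the
#' subthreshold conductances that shape its discharge phenotype. The neuron
#' model is a single compartment with explicit Hodgkin-Huxley style spike
#' currents (full AP waveforms, not integrate-and-fire resets) plus optional
#' inactivating fast/slow A-type potassium, transient low-threshold calcium,
#' hyperpolarisation-activated cation, and slow spike-activated adaptation
#' conductances. No quantitative channel kinetics are claimed: presets are
#' tuned only to express the qualitative discharge definitions.
#'
#' @param discharge_class Intended phenotype label, one of TF, DF, GF, IB,
#'   SS, P, RF (ground truth for classifier validation).
#' @param ahp_profile `"monophasic"`, `"ADP"` or `"slowed"` (qualitative).
#' @param Cm_pF,Rin_MOhm,RMP_mV Passive properties.
#' @param gNa,gK Spike conductances (nS); `VT` shifts the spike threshold.
#' @param gNaP Persistent (non-inactivating) sodium conductance (nS); with
#'   the slow adaptation conductance it supports square-wave bursting
#'   (episodic discharge).
#' @param gKAf,tau_af,tau_hf Fast A-type potassium conductance (nS) and its
#'   activation / inactivation time constants (ms).
#' @param gKAs,tau_as,tau_hs Slow A-type potassium conductance, activation
#'   and inactivation time constants.
#' @param gCaT T-type-like calcium conductance (nS).
#' @param gH Hyperpolarisation-activated cation conductance (nS).
#' @param gW,tau_w_act,tau_w_rec,w_vhalf,w_k Slow adaptation conductance:
#'   sigmoidal steady-state activation centred at `w_vhalf` with slope
#'   `w_k`; relaxes with time constant `tau_w_act` above `w_vhalf` and
#'   `tau_w_rec` below it.
#' @param noise_sd_mV Target standard deviation of the membrane-voltage
#'   fluctuation produced by the injected Ornstein-Uhlenbeck current noise.
#' @param current_class Planted subthreshold current class for voltage-clamp
#'   simulations (`"KA_fast"`, `"KA_slow"`, `"CaT_like"`, `"NC"`), or NA.
#' @return An object of class `"phenotype_spec"`.
#' @export
phenotype_spec <- function(discharge_class = "TF",
                           ahp_profile = "monophasic",
                           Cm_pF = 13, Rin_MOhm = 300, RMP_mV = -65,
                           gNa = 600, gK = 150, VT = -55, gNaP = 0,
                           gKAf = 0, tau_af = 1.5, tau_hf = 100,
                           gKAs = 0, tau_as = 25, tau_hs = 400,
                           gCaT = 0, gH = 0,
                           gW = 0, tau_w_act = 5, tau_w_rec = 300,
                           w_vhalf = -35, w_k = 4,
                           noise_sd_mV = 0.5,
                           current_class = NA_character_) {
  stopifnot(Cm_pF > 0, Rin_MOhm > 0,
            all(c(gNa, gK, gNaP, gKAf, gKAs, gCaT, gH, gW) >= 0))
  spec <- as.list(environment())
  class(spec) <- "phenotype_spec"
  spec
}

## model parameter list consumed by the C++ integrator
spec_params <- function(spec) {
  list(C = spec$Cm_pF, gL = 1000 / spec$Rin_MOhm, EL = spec$RMP_mV,
       gNa = spec$gNa, gK = spec$gK, VT = spec$VT, gNaP = spec$gNaP,
       gKAf = spec$gKAf, tau_af = spec$tau_af, tau_hf = spec$tau_hf,
       gKAs = spec$gKAs, tau_as = spec$tau_as, tau_hs = spec$tau_hs,
       gCaT = spec$gCaT, tau_mT = 2, tau_hT = 40,
       gH = spec$gH, tau_r = 300,
       gW = spec$gW, tau_w_act = spec$tau_w_act,
       tau_w_rec = spec$tau_w_rec, w_vhalf = spec$w_vhalf,
       w_k = spec$w_k)
}

#' Discharge phenotype presets
#'
#' One model cell per discharge class, expressing the qualitative
#' definitions: tonic firing (TF) is the plain spike mechanism; delayed
#' firing (DF) adds a fast A-type conductance whose slow inactivation ramps
#' the onset; gap firing (GF) a slow A-type conductance that spares the
#' onset spike and then pauses discharge; initial bursting (IB) a T-type
#' calcium conductance over a strongly adapting cell; single spiking (SS)
#' a large non-recovering adaptation conductance; phasic (P) a strong slow
#' A-type conductance whose activation is slow enough to spare a short
#' onset discharge episode and whose inactivation later releases a second,
#' sustained episode (discharge interrupted by a silent break);
#' reluctant firing (RF) a large, slowly inactivating A-type conductance
#' that is available at -70 mV but inactivated at depolarised holding.
#'
#' @return Named list of [phenotype_spec()] objects.
#' @export
discharge_presets <- function() {
  list(
    TF = phenotype_spec("TF", gW = 3, tau_w_act = 10, tau_w_rec = 300),
    DF = phenotype_spec("DF", gKAf = 20, tau_hf = 200),
    GF = phenotype_spec("GF", gKAs = 40, tau_as = 40, tau_hs = 350),
    IB = phenotype_spec("IB", gCaT = 8, gW = 14, tau_w_act = 12,
                        tau_w_rec = 1e5),
    SS = phenotype_spec("SS", gW = 60, tau_w_act = 3, tau_w_rec = 1e5),
    P  = phenotype_spec("P", gKAs = 30, tau_as = 100, tau_hs = 250),
    RF = phenotype_spec("RF", gKAf = 120, tau_af = 0.4, tau_hf = 3000)
  )
}

#' Subthreshold current-class presets for voltage clamp
#'
#' @return Named list of [phenotype_spec()] objects whose `current_class`
#'   carries the planted label.
#' @export
subthreshold_presets <- function() {
  list(
    KA_fast = phenotype_spec(gKAf = 5, tau_hf = 60,
                             current_class = "KA_fast"),
    KA_slow = phenotype_spec(gKAs = 5, tau_as = 30, tau_hs = 250,
                             current_class = "KA_slow"),
    CaT_like = phenotype_spec(gCaT = 1.2, current_class = "CaT_like"),
    NC = phenotype_spec(current_class = "NC")
  )
}

## Ornstein-Uhlenbeck current noise whose voltage image has roughly the
## requested sd on a passive membrane: sd_I = sd_V * gL * sqrt((tn + tm)/tn)
ou_noise <- function(n, dt, sd_V, gL, Cm, tau_n = 5) {
  if (sd_V <= 0) return(numeric(n))
  tau_m <- Cm / gL
  sd_I <- sd_V * gL * sqrt((tau_n + tau_m) / tau_n)
  a <- exp(-dt / tau_n)
  b <- sd_I * sqrt(1 - a^2)
  x0 <- stats::rnorm(1, 0, sd_I)
  innov <- stats::rnorm(n - 1)
  x <- stats::filter(b * innov, a, method = "recursive", init = x0)
  c(x0, as.numeric(x))
}

#' Simulate a current-clamp step family
#'
#' Integrates the model under the standard stimulus: 1-s depolarising
#' current steps in 20-pA increments delivered from a -70 mV holding
#' potential (a computed bias current holds the cell there, mirroring the
#' experimental +/- 20 pA bias convention). Internally integrated at
#' `dt_int` (0.01 ms) with 4th-order Runge-Kutta and downsampled to the
#' 10-kHz recording grid. Ground-truth spike times are the depolarisation
#' crossings of the model's own voltage through -20 mV.
#'
#' @param spec A [phenotype_spec()].
#' @param steps_pA Step amplitudes (default 20-300 pA in 20-pA increments).
#' @param holding_mV Holding potential (use about -55 mV for the
#'   depolarised-holding retest of reluctant firing).
#' @param seed Optional RNG seed (noise reproducibility).
#' @param dt_out,dt_int Output and internal sampling intervals (ms).
#' @param pre_ms,step_ms,post_ms Protocol timing.
#' @return List: `sweeps` (current-clamp sweeps with annotated epochs and
#'   `meta$step_pA`), `ground_truth` (`spike_times_ms` per sweep,
#'   `discharge_class`, `holding_mV`).
#' @export
simulate_current_clamp <- function(spec, steps_pA = seq(20, 300, by = 20),
                                   holding_mV = -70, seed = NULL,
                                   dt_out = 0.1, dt_int = 0.01,
                                   pre_ms = 100, step_ms = 1000,
                                   post_ms = 100) {
  stopifnot(inherits(spec, "phenotype_spec"))
  if (dt_int > 0.01 + 1e-12) stop("dt_int must be <= 0.01 ms", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- spec_params(spec)
  bias <- .steady_current_cpp(p, holding_mV)
  n_int <- round((pre_ms + step_ms + post_ms) / dt_int) + 1L
  keep <- round(dt_out / dt_int)
  t_int <- (seq_len(n_int) - 1L) * dt_int
  in_step <- t_int >= pre_ms & t_int < pre_ms + step_ms
  sweeps <- vector("list", length(steps_pA))
  gt_spikes <- vector("list", length(steps_pA))
  ep <- protocol_epochs(
    start_ms = c(0, pre_ms, pre_ms + step_ms),
    duration_ms = c(pre_ms, step_ms, post_ms),
    command_level = c(0, NA, 0), kind = c("holding", "step", "holding"))
  for (i in seq_along(steps_pA)) {
    i_ext <- rep(bias, n_int)
    i_ext[in_step] <- i_ext[in_step] + steps_pA[i]
    i_ext <- i_ext + ou_noise(n_int, dt_int, spec$noise_sd_mV,
                              p$gL, p$C)
    res <- .sim_cc_cpp(p, i_ext, dt_int, keep, holding_mV)
    epi <- ep; epi$command_level[2L] <- steps_pA[i]
    sweeps[[i]] <- sweep_trace(res$V, dt = dt_out, units = "mV",
                               epochs = epi,
                               meta = list(step_pA = steps_pA[i],
                                           holding_mV = holding_mV))
    gt_spikes[[i]] <- res$spike_times_ms
  }
  list(sweeps = sweeps,
       ground_truth = list(spike_times_ms = gt_spikes,
                           discharge_class = spec$discharge_class,
                           holding_mV = holding_mV))
}

#' Simulate the subthreshold voltage-clamp protocol
#'
#' Command waveform: holding at -70 mV, hyperpolarising step to -100 mV
#' (1 s), depolarising step to -40 mV (200 ms), return to holding. Channel
#' gating relaxes exponentially within each constant-command epoch, so the
#' currents are computed analytically (exact, no integration error); spike
#' conductances are omitted (the commands stay subthreshold). P/N subsweeps
#' with 1/n-scaled commands are emitted for the leak-subtraction stage.
#'
#' @param spec A [phenotype_spec()]; its `current_class` is the planted
#'   ground truth.
#' @param seed Optional RNG seed.
#' @param n_pn Number of P/N subsweeps (P/4 default).
#' @param pn_repeats Acquisitions averaged into each emitted subsweep.
#'   Scaling subsweeps up by n multiplies their noise by n as well, so
#'   acquisition protocols repeat and average the scaled pulses; 4
#'   repetitions keep the post-subtraction noise near the raw sweep noise.
#' @param noise_sd_pA Additive white measurement noise.
#' @param holding_mV,hyp_mV,dep_mV,hold_ms,hyp_ms,dep_ms,post_ms Protocol.
#' @param dt Sampling interval (ms).
#' @return List: `test` (full-command current sweep), `subsweeps` (list of
#'   P/N sweeps), `ground_truth` (`current_class`, `ih_present`).
#' @export
simulate_voltage_clamp <- function(spec, seed = NULL, n_pn = 4,
                                   pn_repeats = 4, noise_sd_pA = 1,
                                   holding_mV = -70, hyp_mV = -100,
                                   dep_mV = -40, hold_ms = 100,
                                   hyp_ms = 1000, dep_ms = 200,
                                   post_ms = 100, dt = 0.1) {
  stopifnot(inherits(spec, "phenotype_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- spec_params(spec)
  levels_full <- c(holding_mV, hyp_mV, dep_mV, holding_mV)
  durs <- c(hold_ms, hyp_ms, dep_ms, post_ms)
  ep <- protocol_epochs(
    start_ms = cumsum(c(0, durs[-length(durs)])),
    duration_ms = durs,
    command_level = levels_full,
    kind = c("holding", "step", "step", "holding"))
  make_sweep <- function(levels, repeats = 1L) {
    tr <- vc_currents(p, levels, durs, dt)
    tr <- tr + stats::rnorm(length(tr), 0, noise_sd_pA / sqrt(repeats))
    sweep_trace(tr, dt = dt, units = "pA", epochs = ep,
                meta = list(command_levels = levels))
  }
  test <- make_sweep(levels_full)
  subs <- lapply(seq_len(n_pn), function(i) {
    make_sweep(holding_mV + (levels_full - holding_mV) / n_pn,
               repeats = pn_repeats)
  })
  list(test = test, subsweeps = subs,
       ground_truth = list(current_class = spec$current_class,
                           ih_present = spec$gH > 0))
}

## analytic channel currents under a piecewise-constant command
vc_currents <- function(p, levels, durs, dt) {
  gates <- c("af", "hf", "as", "hs", "mT", "hT", "r")
  ## start from steady state at the first level
  g0 <- .gates_at_cpp(p, levels[1L])
  state <- g0[paste0(gates, "_inf")]
  names(state) <- gates
  out <- numeric(0)
  for (k in seq_along(levels)) {
    v <- levels[k]
    gk <- .gates_at_cpp(p, v)
    n_k <- round(durs[k] / dt)
    tt <- (seq_len(n_k) - 1L) * dt
    x <- lapply(gates, function(g) {
      inf <- gk[[paste0(g, "_inf")]]
      tau <- gk[[paste0("tau_", g)]]
      inf + (state[[g]] - inf) * exp(-tt / tau)
    })
    names(x) <- gates
    i_k <- p$gL * (v - p$EL) +
      p$gKAf * x$af * x$hf * (v + 90) +
      p$gKAs * x$as * x$hs * (v + 90) +
      p$gCaT * x$mT^2 * x$hT * (v - 120) +
      p$gH * x$r * (v + 30)
    ## advance the state to the end of the epoch
    for (g in gates) {
      inf <- gk[[paste0(g, "_inf")]]
      tau <- gk[[paste0("tau_", g)]]
      state[[g]] <- inf + (state[[g]] - inf) * exp(-durs[k] / tau)
    }
    out <- c(out, i_k)
  }
  c(out, out[length(out)])   # close the final sample
}

#' Event-train specification for synthetic sEPSC recordings
#'
#' Defaults reflect typical spinal dorsal horn sEPSC statistics: ~6 Hz,
#' ~-21 pA events with millisecond-scale kinetics, recorded for 30 s.
#'
#' @param rate_Hz Poisson event rate.
#' @param amp_mean_pA,amp_sd_pA Amplitude distribution (negative = inward).
#' @param rise_tau_ms,decay_tau_ms Event kinetics (decay > rise > 0).
#' @param duration_s Recording length (>= 30 s by convention).
#' @param noise_sd_pA Baseline Gaussian noise.
#' @return An `"event_train_spec"` list.
#' @export
event_train_spec <- function(rate_Hz = 6, amp_mean_pA = -21, amp_sd_pA = 5,
                             rise_tau_ms = 0.6, decay_tau_ms = 5,
                             duration_s = 30, noise_sd_pA = 2) {
  stopifnot(rate_Hz >= 0, decay_tau_ms > rise_tau_ms, rise_tau_ms > 0,
            duration_s > 0, noise_sd_pA >= 0)
  structure(as.list(environment()), class = "event_train_spec")
}

#' Synthesize a spontaneous EPSC recording
#'
#' Poisson event times; each event a difference of exponentials scaled to
#' its drawn (inward, negative) amplitude; additive Gaussian baseline noise.
#'
#' @param spec An [event_train_spec()].
#' @param seed Optional RNG seed.
#' @param dt Sampling interval (ms).
#' @return List: `sweep` (pA), `ground_truth` (`onset_times_ms`,
#'   `amplitudes_pA`).
#' @export
synthesize_epsc_trace <- function(spec, seed = NULL, dt = 0.1) {
  stopifnot(inherits(spec, "event_train_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$duration_s * 1000 / dt) + 1L
  y <- stats::rnorm(n, 0, spec$noise_sd_pA)
  n_ev <- stats::rpois(1L, spec$rate_Hz * spec$duration_s)
  times <- amps <- numeric(0)
  if (n_ev > 0) {
    times <- sort(stats::runif(n_ev, 0, spec$duration_s * 1000))
    amps <- stats::rnorm(n_ev, spec$amp_mean_pA, spec$amp_sd_pA)
    amps <- pmin(amps, -1)   # keep events inward
    tker <- seq(0, spec$rise_tau_ms + 8 * spec$decay_tau_ms, by = dt)
    ker <- exp(-tker / spec$decay_tau_ms) - exp(-tker / spec$rise_tau_ms)
    ker <- ker / max(ker)
    for (i in seq_len(n_ev)) {
      i0 <- round(times[i] / dt) + 1L
      idx <- i0:min(i0 + length(ker) - 1L, n)
      y[idx] <- y[idx] + amps[i] * ker[seq_along(idx)]
    }
    times <- (round(times / dt)) * dt   # grid-aligned ground truth
  }
  sw <- sweep_trace(y, dt = dt, units = "pA",
                    meta = list(holding_mV = -70))
  list(sweep = sw,
       ground_truth = list(onset_times_ms = times, amplitudes_pA = amps))
}

#' Synthesize a feature table with planted cluster structure
#'
#' Gaussian clusters whose centroids are placed on a nested binary
#' hierarchy: the closest pair of centroids is exactly `separation`
#' within-cluster standard deviations apart and each higher level of the
#' hierarchy is three times the span of the groups it joins, in a random
#' orientation. The nesting mirrors real multi-parameter panels, where
#' subpopulations differ by less than the major populations do, and it
#' keeps every coarse cut of the dendrogram geometrically unambiguous (an
#' exactly equidistant centroid configuration would make the coarser cuts
#' knife-edge cases for silhouette-based cluster-number selection).
#'
#' @param k Number of clusters (>= 1).
#' @param n_per_cluster Cells per cluster (scalar or length-k).
#' @param separation Centroid separation in units of `within_sd`.
#' @param within_sd Within-cluster standard deviation.
#' @param n_features Feature-space dimension (>= k).
#' @param seed Optional RNG seed.
#' @return List: `table` (a [feature_table()]), `ground_truth` (`labels`).
#' @export
synthesize_feature_table <- function(k, n_per_cluster = 10, separation = 6,
                                     within_sd = 1, n_features = 20,
                                     seed = NULL) {
  stopifnot(k >= 1, n_features >= k)
  if (!is.null(seed)) set.seed(seed)
  n_per <- rep_len(n_per_cluster, k)
  place <- function(k) {
    if (k == 1L) return(matrix(0, 1L, n_features))
    k1 <- ceiling(k / 2); k2 <- k - k1
    a <- place(k1); b <- place(k2)
    u <- stats::rnorm(n_features)
    u <- u / sqrt(sum(u^2))
    span <- function(m) if (nrow(m) == 1L) 0 else max(stats::dist(m))
    gap <- separation * within_sd
    d <- max(gap, 3 * max(span(a), span(b)))
    rbind(sweep(a, 2L, u * d / 2, "-"), sweep(b, 2L, u * d / 2, "+"))
  }
  centroids <- place(k)
  labels <- rep(seq_len(k), n_per)
  vals <- centroids[labels, , drop = FALSE] +
    matrix(stats::rnorm(sum(n_per) * n_features, 0, within_sd),
           sum(n_per), n_features)
  ids <- sprintf("cell_%03d", seq_len(sum(n_per)))
  tab <- feature_table(vals, cell_ids = ids,
                       feature_names = paste0("f", seq_len(n_features)))
  list(table = tab, ground_truth = list(labels = labels))
}

#' Piecewise-analytic action potential fixture
#'
#' Builds a spike of exactly the requested geometry on a quiet baseline:
#' a slow approach ramp, a linear rise from threshold to peak, a falling
#' phase returning to threshold (completing the base width), a descent to
#' the AHP trough at the requested latency, and an exponential recovery
#' toward a depolarised plateau (the inter-spike level of a step response,
#' kept above the trough so the trough is the true post-spike minimum).
#' `profile = "ADP"` inserts a depolarising bump between fast repolarisation
#' and the trough; `"slowed"` makes the falling phase monotone but strongly
#' inflected (a shoulder).
#'
#' @param threshold_mV,peak_mV Spike geometry; `peak_mV > threshold_mV`.
#' @param rise_ms Threshold-to-peak time.
#' @param base_width_ms Width at the threshold voltage (> rise_ms).
#' @param ahp_depth_mV Trough relative to threshold (negative).
#' @param ahp_latency_ms Threshold-to-trough time (> base_width_ms).
#' @param profile `"monophasic"`, `"ADP"` or `"slowed"`.
#' @param baseline_mV Pre-spike baseline.
#' @param dt Sampling interval.
#' @param pre_ms,post_ms Flanking durations.
#' @param on_slow_ahp For the ADP profile: make the post-bump trough deeper
#'   than the pre-bump minimum (the bump rides a developing slow
#'   hyperpolarisation).
#' @return A current-clamp [sweep_trace()].
#' @export
synthesize_ap_waveform <- function(threshold_mV = -40, peak_mV = 20,
                                   rise_ms = 1, base_width_ms = 4,
                                   ahp_depth_mV = -5, ahp_latency_ms = 8,
                                   profile = c("monophasic", "ADP", "slowed"),
                                   baseline_mV = -70, dt = 0.01,
                                   pre_ms = 20, post_ms = 80,
                                   on_slow_ahp = FALSE) {
  profile <- match.arg(profile)
  if (peak_mV <= threshold_mV) stop("peak must exceed threshold", call. = FALSE)
  if (ahp_depth_mV >= 0) stop("ahp_depth_mV must be negative", call. = FALSE)
  if (base_width_ms <= rise_ms) stop("base width must exceed rise", call. = FALSE)
  if (ahp_latency_ms <= base_width_ms) {
    stop("AHP latency must exceed the base width", call. = FALSE)
  }
  slope_rise <- (peak_mV - threshold_mV) / rise_ms
  if (slope_rise < 20) {
    stop("rise slope too shallow for threshold detection", call. = FALSE)
  }
  seg <- function(from, to, dur) {
    n <- round(dur / dt)
    from + (to - from) * seq_len(n) / n
  }
  approach_ms <- (threshold_mV - baseline_mV) / 10   # 10 mV/ms ramp
  fall_ms <- base_width_ms - rise_ms
  v <- c(rep(baseline_mV, round(pre_ms / dt)),
         seg(baseline_mV, threshold_mV, approach_ms))
  v <- c(v, seg(threshold_mV, peak_mV, rise_ms))
  if (profile == "slowed") {
    # three-piece monotone fall with a pronounced shoulder
    drop <- peak_mV - threshold_mV
    v <- c(v,
           seg(peak_mV, peak_mV - 0.45 * drop, 0.2 * fall_ms),
           seg(peak_mV - 0.45 * drop, peak_mV - 0.55 * drop, 0.6 * fall_ms),
           seg(peak_mV - 0.55 * drop, threshold_mV, 0.2 * fall_ms))
  } else {
    v <- c(v, seg(peak_mV, threshold_mV, fall_ms))
  }
  trough <- threshold_mV + ahp_depth_mV
  ahp_ms <- ahp_latency_ms - base_width_ms
  if (profile == "ADP") {
    if (ahp_ms < 16 * dt) stop("AHP latency too short for an ADP bump",
                               call. = FALSE)
    if (on_slow_ahp) {
      # bump riding a developing slow hyperpolarisation: the trough after
      # the bump is deeper than the dip before it
      v_dip <- threshold_mV + 0.4 * ahp_depth_mV
      v_bump <- v_dip + max(1.5, 0.3 * abs(ahp_depth_mV))
      v <- c(v,
             seg(threshold_mV, v_dip, 0.3 * ahp_ms),
             seg(v_dip, v_bump, 0.2 * ahp_ms),
             seg(v_bump, trough, 0.5 * ahp_ms))
      v_last <- trough
    } else {
      # classic ADP: fast AHP dip to the trough, bump, shallower settle
      v_settle <- threshold_mV + 0.55 * ahp_depth_mV
      v_bump <- trough + max(3, 0.7 * abs(ahp_depth_mV))
      v <- c(v,
             seg(threshold_mV, trough, 0.4 * ahp_ms),
             seg(trough, v_bump, 0.25 * ahp_ms),
             seg(v_bump, v_settle, 0.35 * ahp_ms))
      v_last <- v_settle
    }
  } else {
    v <- c(v, seg(threshold_mV, trough, ahp_ms))
    v_last <- trough
  }
  n_post <- round(post_ms / dt)
  plateau <- threshold_mV
  rec <- v_last + (plateau - v_last) * (1 - exp(-(seq_len(n_post) * dt) / 15))
  v <- c(v, rec)
  sweep_trace(v, dt = dt, units = "mV",
              meta = list(profile = profile, threshold_mV = threshold_mV))
}

#' Simulate seal-test sweeps of a passive RC cell
#'
#' Analytic (bin-averaged) current response of a series-resistance /
#' membrane RC circuit to a small voltage step, so the capacitive-transient
#' charge is preserved exactly at the recording sampling rate. A good
#' whole-cell access of 1 MOhm is assumed by default.
#'
#' @param Rin_MOhm,Cm_pF Membrane resistance and capacitance.
#' @param Rs_MOhm Series (access) resistance.
#' @param n_sweeps Number of repeated trials (30 in the standard protocol).
#' @param step_mV Step size (default -5 mV).
#' @param noise_sd_pA Additive white noise per sweep.
#' @param seed Optional RNG seed.
#' @param dt Sampling interval.
#' @return List of voltage-clamp current sweeps with annotated epochs.
#' @export
simulate_seal_test <- function(Rin_MOhm, Cm_pF, Rs_MOhm = 1, n_sweeps = 30,
                               step_mV = -5, noise_sd_pA = 2, seed = NULL,
                               dt = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  hold_ms <- 50; step_ms <- 100; post_ms <- 50
  ep <- protocol_epochs(start_ms = c(0, hold_ms, hold_ms + step_ms),
                        duration_ms = c(hold_ms, step_ms, post_ms),
                        command_level = c(-70, -70 + step_mV, -70),
                        kind = c("holding", "step", "holding"))
  n <- round((hold_ms + step_ms + post_ms) / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  rtot <- Rs_MOhm + Rin_MOhm
  i_ss <- step_mV / rtot * 1000                          # pA
  amp <- step_mV * (1 / Rs_MOhm - 1 / rtot) * 1000       # pA
  tau <- Cm_pF * Rs_MOhm * Rin_MOhm / rtot * 1e-3        # ms
  ## bin-averaged transient: mean over [t0, t1) of amp * exp(-t/tau)
  bin_avg <- function(t_rel) {
    t0 <- pmax(t_rel, 0); t1 <- pmax(t_rel + dt, 0)
    amp * tau / dt * (exp(-t0 / tau) - exp(-t1 / tau))
  }
  base <- numeric(n)
  on <- tt >= hold_ms & tt < hold_ms + step_ms
  base[on] <- i_ss
  base <- base + bin_avg(tt - hold_ms) - bin_avg(tt - hold_ms - step_ms)
  lapply(seq_len(n_sweeps), function(i) {
    sweep_trace(base + stats::rnorm(n, 0, noise_sd_pA), dt = dt,
                units = "pA", epochs = ep)
  })
}

#' Synthesize a long passive current-clamp recording
#'
#' Resting potential plus Ornstein-Uhlenbeck voltage noise, with optional
#' stereotyped action potentials inserted at the given times (for RMP and
#' spontaneous-activity analyses).
#'
#' @param rmp_mV Resting membrane potential.
#' @param duration_s Recording length.
#' @param noise_sd_mV Voltage noise sd.
#' @param spike_times_ms Optional spike times.
#' @param seed Optional RNG seed.
#' @param dt Sampling interval.
#' @return A current-clamp [sweep_trace()].
#' @export
synthesize_passive_trace <- function(rmp_mV = -56, duration_s = 60,
                                     noise_sd_mV = 0.3,
                                     spike_times_ms = NULL, seed = NULL,
                                     dt = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * 1000 / dt) + 1L
  a <- exp(-dt / 10)
  v <- rmp_mV + stats::filter(stats::rnorm(n, 0, noise_sd_mV * sqrt(1 - a^2)),
                              a, method = "recursive", init = 0)
  v <- as.numeric(v)
  if (length(spike_times_ms)) {
    ap <- synthesize_ap_waveform(baseline_mV = rmp_mV, pre_ms = 2,
                                 post_ms = 30, dt = dt)
    ker <- ap$samples - rmp_mV
    # taper the recovery plateau back to baseline
    n_t <- round(20 / dt)
    ker[(length(ker) - n_t + 1L):length(ker)] <-
      ker[(length(ker) - n_t + 1L):length(ker)] *
      rev(seq_len(n_t)) / n_t
    for (t0 in spike_times_ms) {
      i0 <- round(t0 / dt) + 1L
      idx <- i0:min(i0 + length(ker) - 1L, n)
      v[idx] <- v[idx] + ker[seq_along(idx)]
    }
  }
  sweep_trace(v, dt = dt, units = "mV", meta = list(bias_pA = 0))
}
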