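#' Extract the full feature record of one cell
#'
#' Runs every analysis stage on a [cell_record()]: passive properties from
#' the seal-test group, resting potential and spontaneous activity from the
#' long passive recording, rheobase and discharge metrics from the step
#' family (evaluated at rheobase + 40 pA, with the AP threshold taken from
#' the rheobase sweep), discharge-pattern and AHP-profile calls, P/N
#' subtraction and subthreshold current classification, Ih detection, and
#' sliding-template sEPSC statistics. Missing protocol groups simply leave
#' the corresponding features `NA` (recorded in the missingness mask
#' downstream).
#'
#' @param cell A [cell_record()].
#' @param rules Discharge-rule constants, see [discharge_rules()].
#' @return List with `features` (named numeric vector, names aligned with
#'   [default_feature_panel()]), `calls` (pattern, AHP profile, spontaneous
#'   class, subthreshold class, hump flag) and `details` (per-stage raw
#'   results).
#' @export
extract_cell_features <- function(cell, rules = discharge_rules()) {
  stopifnot(inherits(cell, "cell_record"))
  f <- stats::setNames(rep(NA_real_, length(default_feature_panel())),
                       default_feature_panel())
  calls <- list(pattern = NA_character_, ahp_profile = NA_character_,
                spontaneous = NA_character_,
                subthreshold_class = NA_character_, hump = NA)
  details <- list()

  if (!is.null(cell$sweeps$passive_5mV)) {
    pp <- measure_passive(cell$sweeps$passive_5mV)
    f["Rin_MOhm"] <- pp$Rin_MOhm
    f["Cm_pF"] <- pp$Cm_pF
    details$passive <- pp
  }

  if (!is.null(cell$sweeps$passive_60s)) {
    sw <- cell$sweeps$passive_60s[[1L]]
    sp <- detect_spikes(sw)
    f["RMP_mV"] <- suppressWarnings(measure_rmp(sw, sp))
    calls$spontaneous <- classify_spontaneous(sp$peak_time_ms)
    details$spontaneous_spikes <- nrow(sp)
  }

  if (!is.null(cell$sweeps$step_family)) {
    rh <- suppressWarnings(find_rheobase(cell$sweeps$step_family))
    details$rheobase <- rh
    retest <- cell$sweeps$retest_family
    call <- tryCatch(
      classify_discharge(cell$sweeps$step_family, rh, retest, rules),
      error = function(e) discharge_call(NA_character_,
                                         list(error = conditionMessage(e))))
    calls$pattern <- call$pattern
    details$discharge_call <- call
    if (!rh$reluctant_candidate) {
      f["rheobase_pA"] <- rh$rheobase_pA
      ordered <- cell$sweeps$step_family[rh$order]
      eval_idx <- rh$index + 2L
      if (eval_idx <= length(ordered)) {
        sw_eval <- ordered[[eval_idx]]
        st_eval <- rh$spike_trains[[eval_idx]]
        st_rheo <- rh$spike_trains[[rh$index]]
        step <- step_epoch(sw_eval)
        dm <- discharge_metrics(st_eval, step$start_ms, step$duration_ms)
        f["first_spike_latency_ms"] <- dm$first_spike_latency_ms
        f["mean_frequency_Hz"] <- dm$mean_frequency_Hz
        f["mean_instantaneous_frequency_Hz"] <-
          dm$mean_instantaneous_frequency_Hz
        f["adaptation"] <- dm$adaptation
        f["attenuation_pct"] <- dm$attenuation_pct
        f["discharge_duration_ms"] <- dm$discharge_duration_ms
        if (nrow(st_eval)) {
          thr <- if (nrow(st_rheo)) st_rheo$threshold_mV[1L] else NULL
          apf <- ap_waveform_features(sw_eval, st_eval, 1L,
                                      threshold_mV = thr)
          f["ap_threshold_mV"] <- apf$threshold_mV
          f["ap_peak_amplitude_mV"] <- apf$peak_amplitude_mV
          f["ap_rise_ms"] <- apf$rise_ms
          f["ap_base_width_ms"] <- apf$base_width_ms
          f["ahp_amplitude_mV"] <- apf$ahp_amplitude_mV
          f["ahp_latency_ms"] <- apf$ahp_latency_ms
          prof <- classify_ahp_profile(sw_eval, st_eval)
          calls$ahp_profile <- prof$profile
          details$ahp_profile <- prof
        }
        calls$hump <- detect_depolarizing_hump(ordered[[rh$index]],
                                               rh$spike_trains[[rh$index]])
      }
    }
  }

  if (!is.null(cell$sweeps$subthreshold_VC)) {
    grp <- cell$sweeps$subthreshold_VC
    roles <- vapply(grp, function(s) s$meta$role %||% "test", "")
    test <- grp[[which(roles == "test")[1L]]]
    subs <- grp[roles == "pn_sub"]
    corrected <- if (length(subs)) pn_leak_subtract(test, subs) else test
    prof <- classify_subthreshold(corrected)
    calls$subthreshold_class <- prof$current_class
    f["subthreshold_peak_pA"] <-
      if (is.na(prof$peak_amplitude_pA)) 0 else prof$peak_amplitude_pA
    details$subthreshold <- prof
    details$ih <- detect_ih(corrected)
  }

  if (!is.null(cell$sweeps$sepsc_VC)) {
    sw <- cell$sweeps$sepsc_VC[[1L]]
    det <- sliding_template_detect(sw)
    es <- event_statistics(det$onset_times_ms, sw)
    f["sepsc_frequency_Hz"] <- es$frequency_Hz
    f["sepsc_amplitude_pA"] <- es$mean_amplitude_pA
    f["sepsc_tau_ms"] <- es$decay_tau_ms
    details$sepsc <- es
  }

  list(features = f, calls = calls, details = details)
}

#' Simulate a labelled cohort of cells
#'
#' Generates complete cell records (step family, seal test, long passive
#' recording, subthreshold voltage clamp with P/N subsweeps, sEPSC
#' recording) for a set of discharge phenotypes, with per-cell variability
#' drawn around the preset passive properties. Used to exercise the whole
#' pipeline end to end with known ground truth.
#'
#' @param phenotypes Character vector of preset names (see
#'   [discharge_presets()]); one cell is generated per element.
#' @param seed RNG seed.
#' @param identities Optional identity labels per cell (default `"SPBN"`).
#' @param sepsc_duration_s Length of the simulated sEPSC recording.
#' @param passive_duration_s Length of the long passive recording.
#' @return Named list of [cell_record()] objects; ground truth in each
#'   record's `ground_truth` attribute.
#' @export
simulate_cohort <- function(phenotypes, seed = 1, identities = NULL,
                            sepsc_duration_s = 30,
                            passive_duration_s = 35) {
  presets <- discharge_presets()
  stopifnot(all(phenotypes %in% names(presets)))
  if (is.null(identities)) identities <- rep("SPBN", length(phenotypes))
  set.seed(seed)
  cells <- list()
  for (i in seq_along(phenotypes)) {
    spec <- presets[[phenotypes[i]]]
    spec$Rin_MOhm <- spec$Rin_MOhm * stats::runif(1, 0.85, 1.15)
    spec$Cm_pF <- spec$Cm_pF * stats::runif(1, 0.85, 1.15)
    cc <- simulate_current_clamp(spec, seed = sample.int(1e6, 1))
    groups <- list(step_family = cc$sweeps)
    if (phenotypes[i] == "RF") {
      groups$retest_family <-
        simulate_current_clamp(spec, holding_mV = -55,
                               seed = sample.int(1e6, 1))$sweeps
    }
    groups$passive_5mV <- simulate_seal_test(spec$Rin_MOhm, spec$Cm_pF,
                                             seed = sample.int(1e6, 1))
    groups$passive_60s <- list(synthesize_passive_trace(
      rmp_mV = spec$RMP_mV, duration_s = passive_duration_s,
      seed = sample.int(1e6, 1)))
    vc_spec <- spec
    vc <- simulate_voltage_clamp(vc_spec, seed = sample.int(1e6, 1))
    vc$test$meta$role <- "test"
    for (k in seq_along(vc$subsweeps)) vc$subsweeps[[k]]$meta$role <- "pn_sub"
    groups$subthreshold_VC <- c(list(vc$test), vc$subsweeps)
    ep <- synthesize_epsc_trace(
      event_train_spec(duration_s = sepsc_duration_s),
      seed = sample.int(1e6, 1))
    groups$sepsc_VC <- list(ep$sweep)
    id <- sprintf("cell_%02d_%s", i, phenotypes[i])
    cell <- cell_record(id, identity = identities[i],
                        sweeps = groups)
    attr(cell, "ground_truth") <- list(
      discharge_class = phenotypes[i],
      cc = cc$ground_truth, epsc = ep$ground_truth)
    cells[[id]] <- cell
  }
  cells
}
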