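test_that("simulations are deterministic given spec and seed", {
  spec <- discharge_presets()$TF
  a <- simulate_current_clamp(spec, steps_pA = c(80, 120), seed = 9)
  b <- simulate_current_clamp(spec, steps_pA = c(80, 120), seed = 9)
  expect_identical(a$sweeps[[1]]$samples, b$sweeps[[1]]$samples)
  expect_identical(a$ground_truth$spike_times_ms,
                   b$ground_truth$spike_times_ms)

  vc1 <- simulate_voltage_clamp(subthreshold_presets()$KA_slow, seed = 4)
  vc2 <- simulate_voltage_clamp(subthreshold_presets()$KA_slow, seed = 4)
  expect_identical(vc1$test$samples, vc2$test$samples)

  t1 <- synthesize_feature_table(k = 2, n_per_cluster = 5, seed = 17)
  t2 <- synthesize_feature_table(k = 2, n_per_cluster = 5, seed = 17)
  expect_identical(t1$table$values, t2$table$values)
})

test_that("a passive cell stays flat at rest and a driven tonic cell fires throughout", {
  # zero-conductance (leak-only) cell, 0 pA step: flat at RMP, no spikes
  passive <- phenotype_spec(gNa = 0, gK = 0, RMP_mV = -65, noise_sd_mV = 0)
  sim0 <- simulate_current_clamp(passive, steps_pA = 0, holding_mV = -65)
  expect_lt(max(abs(sim0$sweeps[[1]]$samples - (-65))), 0.1)
  expect_length(sim0$ground_truth$spike_times_ms[[1]], 0L)

  # tonic cell well above rheobase: discharge spans >= 80% of the 1-s step
  sim <- simulate_current_clamp(discharge_presets()$TF, seed = 2)
  rh <- suppressWarnings(find_rheobase(sim$sweeps))
  st <- rh$spike_trains[[rh$index + 2L]]
  expect_gte((max(st$peak_time_ms) - min(st$peak_time_ms)) / 1000, 0.8)
})

test_that("gap-firing spec produces a first ISI much longer than the rest", {
  sim <- simulate_current_clamp(discharge_presets()$GF, seed = 4)
  rh <- suppressWarnings(find_rheobase(sim$sweeps))
  st <- rh$spike_trains[[rh$index + 2L]]
  isis <- diff(st$peak_time_ms)
  expect_gt(isis[1], 3 * stats::median(isis[-1]))
})

test_that("voltage-clamp presets express their intended current signatures", {
  # fast A-type: outward transient peaking < 15 ms after the -40 mV step
  vc_f <- simulate_voltage_clamp(subthreshold_presets()$KA_fast, seed = 1,
                                 noise_sd_pA = 0)
  cf <- pn_leak_subtract(vc_f$test, vc_f$subsweeps)
  prof_f <- classify_subthreshold(cf)
  expect_gt(prof_f$peak_amplitude_pA, 0)
  expect_lt(prof_f$latency_ms, 15)

  # T-type-like: transient inward current at -40 mV
  vc_t <- simulate_voltage_clamp(subthreshold_presets()$CaT_like, seed = 1,
                                 noise_sd_pA = 0)
  ct <- pn_leak_subtract(vc_t$test, vc_t$subsweeps)
  expect_lt(classify_subthreshold(ct)$peak_amplitude_pA, 0)

  # leak-only: P/N subtraction leaves nothing
  vc_n <- simulate_voltage_clamp(subthreshold_presets()$NC, seed = 1,
                                 noise_sd_pA = 0)
  cn <- pn_leak_subtract(vc_n$test, vc_n$subsweeps)
  expect_lt(max(abs(cn$samples)), 1e-6)
})

test_that("EPSC trains follow their specification", {
  # rate 0: pure noise, empty event list
  quiet <- synthesize_epsc_trace(event_train_spec(rate_Hz = 0,
                                                  duration_s = 5), seed = 1)
  expect_length(quiet$ground_truth$onset_times_ms, 0L)
  expect_lt(max(abs(quiet$sweep$samples)), 12)   # noise only

  # rate 5 Hz, 30 s: planted count within the Poisson 99% interval of 150
  ep <- synthesize_epsc_trace(event_train_spec(rate_Hz = 5,
                                               duration_s = 30), seed = 2)
  n <- length(ep$ground_truth$onset_times_ms)
  expect_gte(n, qpois(0.005, 150))
  expect_lte(n, qpois(0.995, 150))

  # single noiseless event of -20 pA: trace minimum is -20 at a known time
  spec1 <- event_train_spec(rate_Hz = 1 / 30, amp_mean_pA = -20,
                            amp_sd_pA = 0, noise_sd_pA = 0, duration_s = 30)
  one <- synthesize_epsc_trace(spec1, seed = 8)
  if (length(one$ground_truth$onset_times_ms) > 0) {
    expect_equal(min(one$sweep$samples), -20, tolerance = 1e-6)
  }
  expect_error(event_train_spec(rise_tau_ms = 5, decay_tau_ms = 4), "rise")
})

test_that("planted feature tables have the requested geometry", {
  syn <- synthesize_feature_table(k = 3, n_per_cluster = c(4, 5, 6),
                                  separation = 6, within_sd = 1,
                                  n_features = 10, seed = 33)
  expect_equal(nrow(syn$table$values), 15L)
  expect_equal(as.integer(table(syn$ground_truth$labels)), c(4L, 5L, 6L))
  # centroid distances are close to the requested separation
  cen <- vapply(1:3, function(g) {
    colMeans(syn$table$values[syn$ground_truth$labels == g, , drop = FALSE])
  }, numeric(10))
  d12 <- sqrt(sum((cen[, 1] - cen[, 2])^2))
  expect_equal(d12, 6, tolerance = 0.35 * 6)
})

test_that("analytic AP fixtures validate their geometry", {
  expect_error(synthesize_ap_waveform(peak_mV = -50), "peak")
  expect_error(synthesize_ap_waveform(ahp_depth_mV = 2), "negative")
  expect_error(synthesize_ap_waveform(base_width_ms = 0.5, rise_ms = 1),
               "base width")
  expect_error(synthesize_ap_waveform(ahp_latency_ms = 3, base_width_ms = 4),
               "latency")
})
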