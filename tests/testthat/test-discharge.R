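test_that("classifier recovers every generator phenotype and is deterministic", {
  presets <- discharge_presets()
  for (nm in c("TF", "DF", "GF", "IB", "SS", "P")) {
    for (seed in 1:2) {
      sim <- simulate_current_clamp(presets[[nm]], seed = seed)
      rh <- suppressWarnings(find_rheobase(sim$sweeps))
      call <- classify_discharge(sim$sweeps, rh)
      expect_equal(call$pattern, nm,
                   info = sprintf("%s seed %d", nm, seed))
      # deterministic: the same sweeps always give the same call
      expect_identical(classify_discharge(sim$sweeps, rh)$pattern,
                       call$pattern)
    }
  }
})

test_that("reluctant firing needs a silent family plus a firing depolarised retest", {
  spec <- discharge_presets()$RF
  sim <- simulate_current_clamp(spec, seed = 1)
  rh <- suppressWarnings(find_rheobase(sim$sweeps))
  expect_true(rh$reluctant_candidate)
  retest <- simulate_current_clamp(spec, holding_mV = -55, seed = 2)
  call <- classify_discharge(sim$sweeps, rh, retest$sweeps)
  expect_equal(call$pattern, "RF")
  expect_true(call$evidence$retest_fired)
  # without a firing retest the cell is unclassifiable, not silently RF
  expect_error(classify_discharge(sim$sweeps, rh), "retest")
})

test_that("the call is invariant to permuting the sweep order", {
  sim <- simulate_current_clamp(discharge_presets()$GF, seed = 5)
  base <- classify_discharge(sim$sweeps)
  set.seed(1)
  for (rep in 1:3) {
    perm <- sample(length(sim$sweeps))
    expect_equal(classify_discharge(sim$sweeps[perm])$pattern, base$pattern)
  }
})

test_that("single spiking requires one spike regardless of step amplitude", {
  sim <- simulate_current_clamp(discharge_presets()$SS, seed = 3)
  rh <- suppressWarnings(find_rheobase(sim$sweeps))
  call <- classify_discharge(sim$sweeps, rh)
  expect_equal(call$pattern, "SS")
  expect_lte(call$evidence$max_spikes_suprathreshold, 1L)
})

test_that("gap firing shows an onset spike and a long first interval", {
  sim <- simulate_current_clamp(discharge_presets()$GF, seed = 7)
  call <- classify_discharge(sim$sweeps)
  expect_equal(call$pattern, "GF")
  expect_lte(call$evidence$first_latency_ms, 50)
  expect_gt(call$evidence$first_isi_ratio, 3)
})

test_that("AHP profiles are read from constructed waveforms", {
  mono <- synthesize_ap_waveform(profile = "monophasic", ahp_latency_ms = 12)
  res_m <- classify_ahp_profile(mono, detect_spikes(mono))
  expect_equal(res_m$profile, "monophasic")

  adp <- synthesize_ap_waveform(profile = "ADP", ahp_latency_ms = 14)
  res_a <- classify_ahp_profile(adp, detect_spikes(adp))
  expect_equal(res_a$profile, "ADP")
  expect_false(res_a$evidence$on_slow_ahp)

  # the common case: an ADP superimposed on a developing slow AHP
  adp_slow <- synthesize_ap_waveform(profile = "ADP", ahp_latency_ms = 14,
                                     on_slow_ahp = TRUE)
  res_s <- classify_ahp_profile(adp_slow, detect_spikes(adp_slow))
  expect_equal(res_s$profile, "ADP")
  expect_true(res_s$evidence$on_slow_ahp)

  slowed <- synthesize_ap_waveform(profile = "slowed", base_width_ms = 8,
                                   ahp_latency_ms = 14)
  res_w <- classify_ahp_profile(slowed, detect_spikes(slowed))
  expect_equal(res_w$profile, "slowed")

  # truncated window -> undefined with a flag
  short <- synthesize_ap_waveform(post_ms = 10)
  res_t <- classify_ahp_profile(short, detect_spikes(short))
  expect_true(is.na(res_t$profile))
  expect_true(res_t$evidence$truncated)
})

test_that("depolarising hump detection separates humps from monotone charging", {
  dt <- 0.1
  tt <- seq(0, 1200, by = dt)
  ep <- protocol_epochs(c(0, 100, 1100), c(100, 1000, 100), c(0, 60, 0),
                        c("holding", "step", "holding"))
  # monotone charging to a plateau
  chg <- ifelse(tt >= 100 & tt < 1100, -70 + 20 * (1 - exp(-(tt - 100) / 30)),
                -70)
  expect_false(detect_depolarizing_hump(
    sweep_trace(chg, dt = dt, units = "mV", epochs = ep)))
  # envelope peaking 6 mV above the plateau at 80 ms into the step
  hump <- chg + ifelse(tt >= 100 & tt < 1100,
                       6 * exp(-((tt - 180)^2) / (2 * 40^2)), 0)
  expect_true(detect_depolarizing_hump(
    sweep_trace(hump, dt = dt, units = "mV", epochs = ep)))
})

test_that("synthetic initial-bursting cells show the rheobase hump", {
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_current_clamp(discharge_presets()$IB, seed = seed)
    rh <- suppressWarnings(find_rheobase(sim$sweeps))
    detect_depolarizing_hump(sim$sweeps[[rh$order[rh$index]]])
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
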