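test_that("P/N subtraction cancels a pure ohmic cell and preserves planted transients", {
  spec <- phenotype_spec(current_class = "NC")        # leak only
  vc <- simulate_voltage_clamp(spec, seed = 1, noise_sd_pA = 0)
  corrected <- pn_leak_subtract(vc$test, vc$subsweeps)
  expect_lt(max(abs(corrected$samples)), 1e-6)

  # ohmic + planted biexponential transient survives subtraction unchanged
  tt <- sweep_time(vc$test)
  on <- 1100                                          # -40 mV step onset (ms)
  planted <- ifelse(tt >= on,
                    120 * (exp(-(tt - on) / 30) - exp(-(tt - on) / 4)), 0)
  test2 <- vc$test
  test2$samples <- test2$samples + planted
  corrected2 <- pn_leak_subtract(test2, vc$subsweeps)
  expect_lt(max(abs(corrected2$samples - planted)), 1e-6)

  expect_error(pn_leak_subtract(vc$test, vc$subsweeps, n = 0), "positive")
})

test_that("detection is invariant to adding leak before P/N subtraction", {
  spec <- subthreshold_presets()$KA_fast
  vc <- simulate_voltage_clamp(spec, seed = 2, noise_sd_pA = 0.5)
  base <- classify_subthreshold(pn_leak_subtract(vc$test, vc$subsweeps))
  # add a pure extra leak (scales linearly with the command) to every sweep
  g_extra <- 3   # nS
  add_leak <- function(sw) {
    v_cmd <- command_trace(sw)
    sw$samples <- sw$samples + g_extra * (v_cmd + 60)
    sw
  }
  command_trace <- function(sw) {
    tt <- sweep_time(sw)
    v <- rep(sw$epochs$command_level[1], length(tt))
    for (r in seq_len(nrow(sw$epochs))) {
      e <- sw$epochs[r, ]
      v[tt >= e$start_ms & tt < e$start_ms + e$duration_ms] <- e$command_level
    }
    # subsweep commands are scaled: recover from the stored meta
    if (!is.null(sw$meta$command_levels)) {
      lv <- sw$meta$command_levels
      for (r in seq_len(nrow(sw$epochs))) {
        e <- sw$epochs[r, ]
        v[tt >= e$start_ms & tt < e$start_ms + e$duration_ms] <- lv[r]
      }
    }
    v
  }
  vc2 <- list(test = add_leak(vc$test),
              subsweeps = lapply(vc$subsweeps, add_leak))
  shifted <- classify_subthreshold(pn_leak_subtract(vc2$test, vc2$subsweeps))
  expect_equal(shifted$current_class, base$current_class)
  expect_equal(shifted$peak_amplitude_pA, base$peak_amplitude_pA,
               tolerance = 0.05)
})

test_that("the 15 ms latency boundary separates fast and slow A-currents", {
  make_corrected <- function(latency_peak_ms, amp = 100) {
    durs <- c(100, 1000, 200, 100)
    ep <- protocol_epochs(cumsum(c(0, durs[-4])), durs,
                          c(-70, -100, -40, -70),
                          c("holding", "step", "step", "holding"))
    tt <- seq(0, sum(durs), by = 0.1)
    y <- numeric(length(tt))
    on <- 1100
    # triangular transient peaking exactly at `latency_peak_ms`
    up <- tt >= on & tt <= on + latency_peak_ms
    dn <- tt > on + latency_peak_ms & tt <= on + latency_peak_ms + 40
    y[up] <- amp * (tt[up] - on) / latency_peak_ms
    y[dn] <- amp * (1 - (tt[dn] - on - latency_peak_ms) / 40)
    sweep_trace(y + rnorm(length(y), 0, 0.5), dt = 0.1, units = "pA",
                epochs = ep)
  }
  set.seed(12)
  expect_equal(classify_subthreshold(make_corrected(8))$current_class,
               "KA_fast")
  expect_equal(classify_subthreshold(make_corrected(40))$current_class,
               "KA_slow")
  # exactly 15.0 ms -> slow (the fast definition is strictly < 15 ms)
  expect_equal(classify_subthreshold(make_corrected(15))$current_class,
               "KA_slow")
  # flat trace with noise only -> NC
  set.seed(42)
  flat <- make_corrected(8, amp = 0)
  expect_equal(classify_subthreshold(flat)$current_class, "NC")
})

test_that("planted current classes are recovered from simulated voltage clamp", {
  presets <- subthreshold_presets()
  n_ok <- 0; n_tot <- 0
  for (nm in names(presets)) {
    for (seed in 1:10) {
      vc <- simulate_voltage_clamp(presets[[nm]], seed = seed,
                                   noise_sd_pA = 1)
      prof <- classify_subthreshold(pn_leak_subtract(vc$test, vc$subsweeps))
      n_tot <- n_tot + 1
      n_ok <- n_ok + (prof$current_class == nm)
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("CaT-like currents are inward and measured with latency and half-decay", {
  vc <- simulate_voltage_clamp(subthreshold_presets()$CaT_like, seed = 3,
                               noise_sd_pA = 0.5)
  prof <- classify_subthreshold(pn_leak_subtract(vc$test, vc$subsweeps))
  expect_equal(prof$current_class, "CaT_like")
  expect_lt(prof$peak_amplitude_pA, 0)
  expect_gt(prof$latency_ms, 0)
  expect_gt(prof$half_decay_ms, 0)
})

test_that("Ih sag detection follows the amplitude and noise criteria", {
  durs <- c(100, 1000, 200, 100)
  ep <- protocol_epochs(cumsum(c(0, durs[-4])), durs,
                        c(-70, -100, -40, -70),
                        c("holding", "step", "step", "holding"))
  tt <- seq(0, sum(durs), by = 0.1)
  base <- numeric(length(tt))
  instant <- ifelse(tt >= 100 & tt < 1100, -100, 0)   # pure ohmic step
  sag <- ifelse(tt >= 100 & tt < 1100,
                -20 * (1 - exp(-(tt - 100) / 300)), 0)
  set.seed(5)
  noise <- rnorm(length(tt), 0, 1)
  with_sag <- sweep_trace(instant + sag + noise, dt = 0.1, units = "pA",
                          epochs = ep)
  res <- detect_ih(with_sag)
  expect_true(res$present)
  expect_equal(res$amplitude_pA, 20, tolerance = 0.15 * 20 + 3)

  no_sag <- sweep_trace(instant + noise, dt = 0.1, units = "pA", epochs = ep)
  expect_false(detect_ih(no_sag)$present)

  tiny <- sweep_trace(instant + ifelse(tt >= 100 & tt < 1100, -1, 0) +
                        rnorm(length(tt), 0, 2),
                      dt = 0.1, units = "pA", epochs = ep)
  expect_false(detect_ih(tiny)$present)

  # epoch too short -> undefined with a flag
  ep_short <- protocol_epochs(c(0, 100), c(100, 500), c(-70, -100),
                              c("holding", "step"))
  short <- sweep_trace(rep(0, 6001), dt = 0.1, units = "pA",
                       epochs = ep_short)
  res_short <- detect_ih(short)
  expect_true(is.na(res_short$present))
  expect_equal(res_short$flag, "epoch too short")
})

test_that("simulated Ih cells show a detectable sag in the corrected trace", {
  spec <- phenotype_spec(gH = 1.5, current_class = "NC")
  vc <- simulate_voltage_clamp(spec, seed = 6, noise_sd_pA = 0.5)
  corrected <- pn_leak_subtract(vc$test, vc$subsweeps)
  expect_true(detect_ih(corrected)$present)
})
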