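test_that("spike detection matches a brute-force derivative scan on constructed APs", {
  # three identical analytic APs spliced onto one baseline
  ap <- synthesize_ap_waveform(dt = 0.1, pre_ms = 50, post_ms = 150)
  one <- ap$samples - (-70)
  n_ap <- length(one)
  v <- rep(-70, 3 * n_ap)
  starts <- c(0, n_ap, 2 * n_ap)
  for (s in starts) v[(s + 1):(s + n_ap)] <- -70 + one
  sw <- sweep_trace(v, dt = 0.1)
  st <- detect_spikes(sw)
  expect_equal(nrow(st), 3L)
  # brute-force scan of the centered-difference derivative array
  dvdt <- (v[-(1:2)] - v[1:(length(v) - 2)]) / 0.2
  first_idx <- which(dvdt >= 15)[1] + 1L
  expect_lt(abs(st$threshold_time_ms[1] - (first_idx - 1) * 0.1), 0.11)
  expect_true(all(st$threshold_time_ms < st$peak_time_ms))
  expect_true(all(diff(st$threshold_time_ms) > 0))
})

test_that("flat and sub-criterion ramp traces contain no spikes", {
  expect_equal(nrow(detect_spikes(sweep_trace(rep(-70, 1000)))), 0L)
  ramp <- sweep_trace(seq(-70, -70 + 0.1 * 999 * 10, length.out = 1000) * 0 +
                        -70 + (0:999) * 0.1 * 10, dt = 0.1)  # 10 mV/ms
  expect_equal(nrow(detect_spikes(ramp)), 0L)
})

test_that("fast passive charging of a strong step is not mistaken for a spike", {
  # 25 mV/ms rise to a subthreshold plateau, no regenerative event
  v <- c(rep(-70, 100), pmin(-70 + (0:500) * 0.1 * 25, -40), rep(-40, 400))
  expect_equal(nrow(detect_spikes(sweep_trace(v, dt = 0.1))), 0L)
})

test_that("detected spikes equal the model's own spike count across phenotypes", {
  presets <- discharge_presets()
  for (nm in c("TF", "DF", "GF", "IB")) {
    for (seed in 1:3) {
      spec <- presets[[nm]]
      spec$noise_sd_mV <- 0.5
      sim <- simulate_current_clamp(spec, steps_pA = c(120, 160), seed = seed)
      for (i in seq_along(sim$sweeps)) {
        st <- detect_spikes(sim$sweeps[[i]])
        expect_equal(nrow(st), length(sim$ground_truth$spike_times_ms[[i]]),
                     info = sprintf("%s seed %d sweep %d", nm, seed, i))
      }
    }
  }
})

test_that("passive properties recover an ideal resistor and simulated RC cells", {
  # ideal 300 MOhm resistor: flat -16.667 pA step response
  ep <- protocol_epochs(c(0, 50, 150), c(50, 100, 50), c(-70, -75, -70),
                        c("holding", "step", "holding"))
  i_ss <- -5 / 300 * 1000
  v <- c(rep(0, 500), rep(i_ss, 1000), rep(0, 501))
  sw <- sweep_trace(v, dt = 0.1, units = "pA", epochs = ep)
  pp <- measure_passive(list(sw))
  expect_equal(pp$Rin_MOhm, 300, tolerance = 1e-6)

  # simulated RC cells across the study grid
  for (rin in c(100, 300, 600)) {
    for (cm in c(5, 13, 25)) {
      sweeps <- simulate_seal_test(rin, cm, seed = rin + cm)
      pp <- measure_passive(sweeps)
      expect_lt(abs(pp$Rin_MOhm - rin) / rin, 0.05)
      expect_lt(abs(pp$Cm_pF - cm) / cm, 0.05)
    }
  }
  no_step <- sweep_trace(rep(0, 101), units = "pA",
                         epochs = protocol_epochs(0, 10, -70, "holding"))
  expect_error(measure_passive(list(no_step)), "step")
})

test_that("RMP is the spike-masked mean and short recordings warn", {
  flat <- sweep_trace(rep(-56, 35 * 10000), dt = 0.1)
  expect_equal(measure_rmp(flat), -56)
  spiky <- synthesize_passive_trace(rmp_mV = -60, duration_s = 35,
                                    noise_sd_mV = 0.2,
                                    spike_times_ms = c(5000, 12000, 23000),
                                    seed = 4)
  st <- detect_spikes(spiky)
  expect_equal(nrow(st), 3L)
  expect_lt(abs(measure_rmp(spiky, st) - (-60)), 0.5)
  short <- sweep_trace(rep(-56, 10 * 10000), dt = 0.1)
  expect_warning(measure_rmp(short), "30 s")
})

test_that("spontaneous activity classes follow CV and burst structure", {
  expect_equal(classify_spontaneous(numeric(0)), "none")
  periodic <- seq(0, 60000, by = 500)          # 2 Hz clock
  expect_equal(classify_spontaneous(periodic), "tonic")
  set.seed(21)
  pois <- cumsum(stats::rexp(120, rate = 2 / 1000))  # rate 2 Hz in ms
  expect_equal(classify_spontaneous(pois), "irregular")
  bursts <- c(0, 50, 100, 150, 3000, 3050, 3100, 3160, 7000, 7040, 7090)
  expect_equal(classify_spontaneous(bursts), "bursting")
})

test_that("rheobase is the smallest spiking step with boundary and reluctant flags", {
  sim <- simulate_current_clamp(discharge_presets()$TF, seed = 2)
  rh <- find_rheobase(sim$sweeps)
  n_spikes <- vapply(sim$ground_truth$spike_times_ms, length, 1L)
  expect_equal(rh$rheobase_pA,
               seq(20, 300, by = 20)[min(which(n_spikes > 0))])
  # no spiking anywhere -> reluctant candidate, not an error
  quiet <- lapply(c(20, 40), function(a) {
    make_step_sweep(rep(-70, 12001), step_pA = a)
  })
  rq <- find_rheobase(quiet)
  expect_true(rq$reluctant_candidate)
  expect_true(is.na(rq$rheobase_pA))
})

test_that("discharge metrics follow their definitions on constructed trains", {
  st <- data.frame(threshold_time_ms = c(220, 269, 319, 419),
                   threshold_mV = rep(-40, 4),
                   peak_time_ms = c(221, 270, 320, 420),
                   peak_mV = -40 + c(60, 55, 50, 45))
  dm <- discharge_metrics(st, step_start_ms = 100, step_duration_ms = 1000)
  expect_equal(dm$first_spike_latency_ms, 120)
  expect_equal(dm$isis_ms, c(49, 50, 100))
  expect_equal(dm$adaptation, (1000 / 100) / (1000 / 49))
  expect_equal(dm$attenuation_pct, 100 * 45 / 60)
  expect_equal(dm$discharge_duration_ms, 199)
  expect_equal(dm$mean_frequency_Hz, 4)

  # constant-ISI and constant-peak trains: adaptation 1, attenuation 100%
  st2 <- data.frame(threshold_time_ms = c(100, 200, 300),
                    threshold_mV = rep(-40, 3),
                    peak_time_ms = c(101, 201, 301), peak_mV = rep(20, 3))
  dm2 <- discharge_metrics(st2, 100, 1000)
  expect_equal(dm2$adaptation, 1)
  expect_equal(dm2$attenuation_pct, 100)

  one <- discharge_metrics(st2[1, ], 100, 1000)
  expect_false(one$defined)
  expect_true(is.na(one$adaptation))
})

test_that("metrics are invariant to shifting the time axis", {
  st <- data.frame(threshold_time_ms = c(220, 320, 470),
                   threshold_mV = rep(-40, 3),
                   peak_time_ms = c(221, 321, 471),
                   peak_mV = c(20, 18, 15))
  base <- discharge_metrics(st, 100, 1000)
  shift <- st
  shift$threshold_time_ms <- shift$threshold_time_ms + 5000
  shift$peak_time_ms <- shift$peak_time_ms + 5000
  moved <- discharge_metrics(shift, 5100, 1000)
  for (fld in c("first_spike_latency_ms", "adaptation", "attenuation_pct",
                "discharge_duration_ms", "mean_frequency_Hz")) {
    expect_equal(moved[[fld]], base[[fld]])
  }
})

test_that("AP waveform features read constructed geometry exactly", {
  sw <- synthesize_ap_waveform(threshold_mV = -40, peak_mV = 20,
                               rise_ms = 1, base_width_ms = 4,
                               ahp_depth_mV = -5, ahp_latency_ms = 8,
                               dt = 0.01)
  st <- detect_spikes(sw)
  f <- ap_waveform_features(sw, st)
  expect_equal(f$threshold_mV, -40, tolerance = 0.15)
  expect_equal(f$peak_amplitude_mV, 60, tolerance = 0.2)
  expect_equal(f$rise_ms, 1, tolerance = 0.05)
  expect_equal(f$base_width_ms, 4, tolerance = 0.05)
  expect_equal(f$ahp_amplitude_mV, -5, tolerance = 0.2)
  expect_equal(f$ahp_latency_ms, 8, tolerance = 0.1)

  # symmetric triangular AP with 2 ms half-rise has a 4 ms base width
  tri <- synthesize_ap_waveform(threshold_mV = -40, peak_mV = 20,
                                rise_ms = 2, base_width_ms = 4,
                                ahp_depth_mV = -5, ahp_latency_ms = 10,
                                dt = 0.01)
  ft <- ap_waveform_features(tri, detect_spikes(tri))
  expect_equal(ft$base_width_ms, 4, tolerance = 0.05)
})

test_that("simulated tonic cell features agree with the noise-free reference", {
  spec <- discharge_presets()$TF
  spec$noise_sd_mV <- 0
  ref <- simulate_current_clamp(spec, steps_pA = c(80, 100, 120), seed = 1)
  rh <- suppressWarnings(find_rheobase(ref$sweeps))
  sw <- ref$sweeps[[rh$index]]
  st <- rh$spike_trains[[rh$index]]
  f_ref <- ap_waveform_features(sw, st)

  spec$noise_sd_mV <- 0.5
  noisy <- simulate_current_clamp(spec, steps_pA = c(80, 100, 120), seed = 1)
  stn <- detect_spikes(noisy$sweeps[[rh$index]])
  f_noisy <- ap_waveform_features(noisy$sweeps[[rh$index]], stn)
  expect_lt(abs(f_noisy$peak_amplitude_mV - f_ref$peak_amplitude_mV) /
              f_ref$peak_amplitude_mV, 0.05)
  expect_lt(abs(f_noisy$threshold_mV - f_ref$threshold_mV), 2)
})
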