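test_that("generator produces the configured length and breath count", {
  sim <- generate_ppg(synth_config(duration_s = 60, sampling_rate = 125,
                                   heart_rate = 75, resp_rate = 15, seed = 1))
  expect_equal(nrow(sim$signal), 7500)
  expect_equal(nrow(sim$breaths), 15)
  expect_true(all(diff(sim$breaths$onset_s) > 0))
})

test_that("identical configs give bit-identical signals", {
  cfg <- synth_config(duration_s = 30, noise_sd = 0.05, seed = 99)
  a <- generate_ppg(cfg)
  b <- generate_ppg(cfg)
  expect_identical(a$signal$amplitude, b$signal$amplitude)
  expect_identical(a$breaths, b$breaths)
})

test_that("onset count over integer minutes matches the configured rate", {
  for (rr in c(8, 15, 22)) {
    sim <- generate_ppg(synth_config(duration_s = 180, resp_rate = rr, seed = 2))
    for (m in 1:3) {
      n_on <- sum(sim$breaths$onset_s >= (m - 1) * 60 & sim$breaths$onset_s < m * 60)
      expect_equal(n_on, rr, tolerance = 1e-9)
    }
  }
  # a fractional rate must still be consistent over a whole-breath span
  sim <- generate_ppg(synth_config(duration_s = 120, resp_rate = 12.5, seed = 2))
  expect_equal(sum(sim$breaths$onset_s < 120), 25)
})

test_that("without modulation all pulse amplitudes are equal", {
  sim <- generate_ppg(synth_config(duration_s = 60, heart_rate = 72,
                                   resp_rate = 15, bw_depth = 0, am_depth = 0,
                                   fm_depth = 0, seed = 3))
  beats <- segment_pulses(lowpass_ppg(sim$signal))
  amp <- beats$peak_amp - beats$trough_amp
  expect_lt(diff(range(amp)) / stats::median(amp), 0.02)
})

test_that("the baseline component peaks at the respiratory frequency", {
  sim <- generate_ppg(synth_config(duration_s = 120, resp_rate = 12,
                                   bw_depth = 0.2, am_depth = 0, fm_depth = 0,
                                   seed = 4))
  # moving-mean baseline over one cardiac cycle
  fs <- 125
  k <- round(fs * 60 / 75)
  base <- stats::filter(sim$signal$amplitude, rep(1 / k, k), sides = 2)
  base <- base[!is.na(base)]
  f_dom <- dominant_freq(base, fs)
  expect_lt(abs(f_dom - 0.2), 1 / 120 + 1e-9)  # within one frequency bin
})

test_that("each modulation route alone is recoverable at the breathing frequency", {
  depths <- list(am = c(0, 0.15, 0), fm = c(0, 0, 0.15), bw = c(0.15, 0, 0))
  for (kind in names(depths)) {
    d <- depths[[kind]]
    sim <- generate_ppg(synth_config(duration_s = 120, heart_rate = 75,
                                     resp_rate = 15, bw_depth = d[1],
                                     am_depth = d[2], fm_depth = d[3], seed = 5))
    beats <- segment_pulses(lowpass_ppg(highpass_vlf(sim$signal)))
    resp <- resample_features(beat_features(beats, kind), "linear", 4)
    expect_equal(rr_spectral(resp)$rr, 15, tolerance = 0.5,
                 label = paste(kind, "route"))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(duration_s = 0), class = "respyre_config_error")
  expect_error(synth_config(duration_s = 60, resp_rate = 2),
               class = "respyre_config_error")
  expect_error(synth_config(duration_s = 60, bw_depth = 1.5),
               class = "respyre_config_error")
})

test_that("artifacts change only the targeted interval", {
  sim <- generate_ppg(synth_config(duration_s = 60, seed = 6))
  w <- sim$signal
  base_max <- max(abs(w$amplitude))

  spiked <- inject_artifact(w, 10, 0.5, "spike", magnitude = 10 * base_max)
  expect_gte(max(abs(spiked$amplitude)) / base_max, 5)
  outside <- w$time < 10 | w$time >= 10.5
  expect_identical(spiked$amplitude[outside], w$amplitude[outside])

  expect_identical(inject_artifact(w, 10, 5, "step", magnitude = 0)$amplitude,
                   w$amplitude)

  dropped <- inject_artifact(w, 20, 5, "dropout")
  seg <- dropped$amplitude[dropped$time >= 20 & dropped$time < 25]
  expect_equal(stats::var(seg), 0)

  expect_error(inject_artifact(w, 58, 5, "spike"), class = "respyre_signal_error")
})

test_that("a piecewise respiratory schedule changes the onset spacing", {
  sched <- data.frame(start_s = c(0, 60), rate = c(10, 20))
  sim <- generate_ppg(synth_config(duration_s = 120, resp_rate = sched, seed = 7))
  first <- sum(sim$breaths$onset_s < 60)
  second <- sum(sim$breaths$onset_s >= 60)
  expect_equal(first, 10, tolerance = 1)
  expect_equal(second, 20, tolerance = 1)
})
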