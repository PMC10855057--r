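test_that("pulse segmentation finds one beat per cardiac cycle", {
  sim <- generate_ppg(synth_config(duration_s = 60, heart_rate = 60,
                                   resp_rate = 15, bw_depth = 0, am_depth = 0,
                                   fm_depth = 0, seed = 1))
  beats <- segment_pulses(lowpass_ppg(sim$signal))
  expect_gte(nrow(beats), 59)
  expect_lte(nrow(beats), 61)
  expect_true(all(diff(beats$peak_idx) > 0))
  expect_true(all(beats$trough_idx < beats$peak_idx))
})

test_that("a flat signal yields no beats, with a warning", {
  flat <- wave_signal(numeric(125 * 10), fs = 125)
  expect_warning(beats <- segment_pulses(flat), "No pulses")
  expect_equal(nrow(beats), 0)
})

test_that("a large spike is detected as a beat but artifact-flagged", {
  sim <- generate_ppg(synth_config(duration_s = 60, heart_rate = 75,
                                   resp_rate = 15, seed = 3,
                                   artifacts = list(list(start_s = 10, duration_s = 0.5,
                                                         kind = "spike", magnitude = 10))))
  beats <- segment_pulses(lowpass_ppg(sim$signal))
  near <- beats$peak_s > 9.5 & beats$peak_s < 11
  expect_true(any(beats$artifact[near]))
  expect_false(any(beats$artifact[beats$peak_s > 20]))
})

test_that("beat count is stable under 5% noise", {
  base <- synth_config(duration_s = 60, heart_rate = 75, resp_rate = 15,
                       noise_sd = 0, seed = 4)
  noisy <- synth_config(duration_s = 60, heart_rate = 75, resp_rate = 15,
                        noise_sd = 0.05, seed = 4)
  n0 <- nrow(segment_pulses(lowpass_ppg(generate_ppg(base)$signal)))
  n1 <- nrow(segment_pulses(lowpass_ppg(generate_ppg(noisy)$signal)))
  expect_lte(abs(n1 - n0) / n0, 0.02)
})

test_that("feature series track their modulation route", {
  sim <- generate_ppg(synth_config(duration_s = 120, heart_rate = 75,
                                   resp_rate = 15, seed = 5))
  beats <- segment_pulses(lowpass_ppg(highpass_vlf(sim$signal)))
  for (kind in c("am", "fm", "bw", "peak_amplitude", "trough_mean")) {
    fser <- beat_features(beats, kind)
    expect_true(all(diff(fser$time) > 0))
  }
  # am and fm periodograms peak at 0.25 Hz
  for (kind in c("am", "fm")) {
    resp <- resample_features(beat_features(beats, kind), "linear", 4)
    expect_lt(abs(dominant_freq(resp$amplitude, 4) - 0.25), 0.01)
  }
})

test_that("an unmodulated train gives a flat peak-amplitude series", {
  sim <- generate_ppg(synth_config(duration_s = 60, heart_rate = 75,
                                   resp_rate = 15, bw_depth = 0, am_depth = 0,
                                   fm_depth = 0, seed = 6))
  beats <- segment_pulses(lowpass_ppg(sim$signal))
  fser <- beat_features(beats, "peak_amplitude")
  expect_lt(stats::sd(fser$value) / mean(fser$value), 0.02)
})

test_that("only the matching feature series peaks at the breathing frequency", {
  # amplitude-only modulation: the am series must carry the largest
  # respiratory spectral peak of the three
  sim <- generate_ppg(synth_config(duration_s = 120, heart_rate = 75,
                                   resp_rate = 15, bw_depth = 0,
                                   am_depth = 0.15, fm_depth = 0, seed = 7))
  beats <- segment_pulses(lowpass_ppg(highpass_vlf(sim$signal)))
  peak_power <- sapply(c("am", "fm", "bw"), function(k) {
    resp <- resample_features(beat_features(beats, k), "linear", 4)
    sp <- welch_psd(resp$amplitude, 4)
    # normalised power at the respiratory frequency
    max(sp$power[abs(sp$frequency - 0.25) < 0.03]) / sum(sp$power)
  })
  expect_equal(names(which.max(peak_power)), "am")
})

test_that("interpolation methods follow their definitions", {
  ser <- tibble::tibble(time = c(0, 1), value = c(0, 2))
  lin <- resample_features(ser, "linear", 4, bandpass = FALSE)
  expect_equal(lin$amplitude, c(0, 0.5, 1.0, 1.5, 2.0))

  # cubic spline interpolates through the knots
  tt <- seq(0, 10, by = 0.5)
  ser2 <- tibble::tibble(time = tt, value = sin(2 * pi * 0.25 * tt))
  sp <- resample_features(ser2, "cubic_spline", 4, bandpass = FALSE)
  at_knots <- sp$amplitude[match(tt, sp$time)]
  expect_equal(at_knots, ser2$value, tolerance = 1e-9)

  expect_error(resample_features(ser, "nearest"), "should be one of")
  expect_error(resample_features(ser[1, ], "linear"), class = "respyre_data_error")
})

test_that("all resampling methods preserve a sinusoidal feature's frequency", {
  # beat-like sampling: roughly one point per 0.6 s with mild jitter
  tt <- seq(0, 100, by = 0.6) + withr::with_seed(8, runif(167, -0.05, 0.05))
  tt <- sort(tt)
  ser <- tibble::tibble(time = tt, value = sin(2 * pi * 0.15 * tt))
  for (m in c("linear", "cubic_spline", "berger")) {
    resp <- resample_features(ser, m, 4)
    expect_lt(abs(dominant_freq(resp$amplitude, 4) - 0.15), 0.02, label = m)
  }
  # linear and cubic spline agree closely on smooth series
  lin <- resample_features(ser, "linear", 4, bandpass = FALSE)$amplitude
  spl <- resample_features(ser, "cubic_spline", 4, bandpass = FALSE)$amplitude
  expect_lt(sqrt(mean((lin - spl)^2)) / sqrt(mean(spl^2)), 0.05)
})

test_that("filter-based extraction recovers baseline-wander breathing", {
  sim <- generate_ppg(synth_config(duration_s = 120, resp_rate = 12,
                                   bw_depth = 0.2, seed = 9))
  resp <- extract_filter_based(sim$signal)
  expect_lt(abs(dominant_freq(resp$amplitude, 4) - 0.2), 0.01)
  expect_identical(attr(resp, "provenance"), "filter_based")

  z <- wave_signal(numeric(1250), fs = 125)
  expect_equal(max(abs(extract_filter_based(z)$amplitude)), 0)

  # without modulation the respiratory bin holds far less power
  flat <- generate_ppg(synth_config(duration_s = 120, resp_rate = 12,
                                    bw_depth = 0, am_depth = 0, fm_depth = 0,
                                    seed = 9))
  pow_at <- function(w) {
    sp <- welch_psd(w$amplitude, 4)
    max(sp$power[abs(sp$frequency - 0.2) < 0.02])
  }
  expect_lt(pow_at(extract_filter_based(flat$signal)),
            0.1 * pow_at(resp))
})
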