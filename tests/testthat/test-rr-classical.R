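test_that("zero-crossing counting matches sinusoid frequencies", {
  expect_equal(rr_zero_crossing(sine_wave(0.25, 4, 60), c(0, 60))$rr, 15)
  expect_equal(rr_zero_crossing(sine_wave(8 / 60, 4, 60), c(0, 60))$rr, 8)

  zero <- wave_signal(numeric(240), fs = 4)
  expect_false(rr_zero_crossing(zero, c(0, 60))$valid)
  expect_error(rr_zero_crossing(sine_wave(0.25, 4, 60), c(0, 120)),
               class = "respyre_signal_error")
})

test_that("trough-peak detection counts whole breath cycles", {
  expect_equal(rr_trough_peak(sine_wave(0.2, 4, 60), c(0, 60))$rr, 12)

  noisy <- withr::with_seed(2, {
    x <- sine_wave(0.25, 4, 60)
    wave_update_ <- x$amplitude + rnorm(240, sd = 0.05)
    wave_signal(wave_update_, fs = 4)
  })
  est <- rr_trough_peak(noisy, c(0, 60))
  expect_equal(est$rr, 15, tolerance = 1 / 15)

  ramp <- wave_signal(seq(-1, 1, length.out = 240), fs = 4)
  expect_false(rr_trough_peak(ramp, c(0, 60))$valid)
})

test_that("spectral estimation finds the dominant in-band peak", {
  expect_equal(rr_spectral(sine_wave(0.3, 4, 60), c(0, 60))$rr, 18,
               tolerance = 0.5 / 18)

  # the larger-magnitude component wins
  t <- seq(0, 60 - 0.25, by = 0.25)
  two <- wave_signal(sin(2 * pi * 0.2 * t) + 0.3 * sin(2 * pi * 0.4 * t), fs = 4)
  expect_equal(rr_spectral(two, c(0, 60))$rr, 12, tolerance = 0.5 / 12)

  noise <- withr::with_seed(3, wave_signal(rnorm(240), fs = 4))
  est <- rr_spectral(noise, c(0, 60))
  expect_true(est$low_confidence)
  tone <- rr_spectral(sine_wave(0.3, 4, 60), c(0, 60))
  expect_false(tone$low_confidence)
})

test_that("welch spectrum matches the single-segment periodogram oracle", {
  x <- withr::with_seed(4, rnorm(256))
  fs <- 4
  sp <- welch_psd(x, fs, seg_s = 64, df_bpm = 60 * fs / 256)
  # oracle: direct Hann-tapered periodogram of the demeaned series
  w <- 0.5 - 0.5 * cos(2 * pi * (0:255) / 255)
  xt <- (x - mean(x)) * w
  p_oracle <- Mod(stats::fft(xt)[1:129])^2 / (fs * sum(w^2))
  expect_equal(sp$power, p_oracle, tolerance = 1e-12)
})

test_that("smart fusion averages on agreement and abstains on spread", {
  f <- smart_fusion(c(10, 11, 12))
  expect_true(f$valid)
  expect_equal(f$rr, 11)

  expect_false(smart_fusion(c(5, 15, 25))$valid)

  f3 <- smart_fusion(c(14, 14, 14))
  expect_true(f3$valid)
  expect_equal(f3$rr, 14)

  # fused value lies within the input range
  for (s in 1:20) {
    vals <- withr::with_seed(s, runif(3, 4, 60))
    f <- smart_fusion(vals)
    if (f$valid) {
      expect_gte(f$rr, min(vals))
      expect_lte(f$rr, max(vals))
    }
  }

  expect_error(smart_fusion(c(10, 12)), class = "respyre_config_error")
  # invalid inputs propagate
  ests <- dplyr::bind_rows(
    rr_spectral(sine_wave(0.25, 4, 60), c(0, 60)),
    rr_spectral(sine_wave(0.25, 4, 60), c(0, 60)),
    rr_zero_crossing(wave_signal(numeric(240), 4), c(0, 60))
  )
  expect_false(smart_fusion(ests)$valid)
})

test_that("peak-conditioned averaging excludes diffuse spectra", {
  grid <- seq(0, 1, by = 1 / 120)
  peaked <- function(f0) exp(-(grid - f0)^2 / (2 * 0.02^2))
  flat <- rep(1, length(grid))
  mk <- function(p, id) tibble::tibble(series = id, frequency = grid, power = p)

  three <- dplyr::bind_rows(mk(peaked(0.25), "a"), mk(peaked(0.25), "b"),
                            mk(peaked(0.25), "c"))
  est <- spectral_peak_average(three)
  expect_true(est$valid)
  expect_equal(est$rr, 15, tolerance = 0.5 / 15)
  expect_equal(est$n_included, 3L)

  mixed <- dplyr::bind_rows(mk(peaked(0.25), "a"), mk(peaked(0.25), "b"),
                            mk(flat, "c"))
  est2 <- spectral_peak_average(mixed)
  expect_equal(est2$n_included, 2L)
  expect_equal(est2$rr, 15, tolerance = 0.5 / 15)

  allflat <- dplyr::bind_rows(mk(flat, "a"), mk(flat, "b"))
  expect_false(spectral_peak_average(allflat)$valid)

  bad <- dplyr::bind_rows(mk(peaked(0.25), "a"),
                          tibble::tibble(series = "b", frequency = grid[-1],
                                         power = peaked(0.25)[-1]))
  expect_error(spectral_peak_average(bad), class = "respyre_format_error")
})

test_that("temporal fusion takes the median of recent valid estimates", {
  expect_equal(temporal_fusion(c(15, 16, 14))$rr, 15)
  expect_equal(temporal_fusion(15)$rr, 15)
  expect_equal(temporal_fusion(c(15, NA, 17))$rr, 16)
  expect_false(temporal_fusion(c(NA_real_, NA_real_))$valid)
  expect_error(temporal_fusion(numeric(0)), class = "respyre_config_error")

  sm <- temporal_smooth(tibble::tibble(rr = c(10, 30, 11, 12),
                                       valid = c(TRUE, TRUE, TRUE, TRUE)))
  # the single outlier at position 2 is damped by the trailing median
  expect_equal(sm$rr_smooth, c(10, 20, 11, 12))
})

test_that("estimators agree on noise-free sinusoids", {
  for (rr in c(8, 15, 24)) {
    w <- sine_wave(rr / 60, 4, 120)
    zc <- rr_zero_crossing(w, c(0, 120))$rr
    tp <- rr_trough_peak(w, c(0, 120))$rr
    sp <- rr_spectral(w, c(0, 120))$rr
    expect_equal(zc, rr, tolerance = 1 / rr)
    expect_equal(tp, rr, tolerance = 1 / rr)
    expect_equal(sp, rr, tolerance = 0.5 / rr)
  }
})
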