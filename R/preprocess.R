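#' @name preprocess
#' @title Preprocessing: filtering, resampling, scaling, windowing
#'
#' @description
#' All filters are order-4 Butterworth responses applied with zero phase
#' (forward-backward equivalent), realised in the frequency domain on a
#' mirror-padded FFT so no group delay or start-up transient is introduced.
#' Cutoffs are pre-warped so that the cascaded (zero-phase) response is -3 dB
#' at the nominal cutoff frequency.
#'
#' @param signal A `resp_wave` or a data frame with `time`/`amplitude`
#'   columns.
#' @return A `resp_wave` of the same length and sampling rate.
NULL

# squared-magnitude (zero-phase) Butterworth gain at frequencies f (Hz).
# Cutoffs are adjusted so the *cascaded* response is -3 dB at the nominal
# values: for |H|^2 = 1/(1 + (f/fc)^(2n)), requiring |H(f3)|^2 = 2^(-1/2)
# gives fc = f3 / (sqrt(2) - 1)^(1/(2n)) for a low-pass (reciprocal for a
# high-pass edge).
butter_gain2 <- function(f, lo = NULL, hi = NULL, order = 4) {
  corr <- (sqrt(2) - 1)^(1 / (2 * order))
  g <- rep(1, length(f))
  if (!is.null(hi)) {                      # low-pass edge at `hi`
    fc <- hi / corr
    g <- g / (1 + (f / fc)^(2 * order))
  }
  if (!is.null(lo)) {                      # high-pass edge at `lo`
    fc <- lo * corr
    fr <- ifelse(f == 0, Inf, fc / f)
    g <- g / (1 + fr^(2 * order))
  }
  g
}

# apply a real, even frequency-domain gain to x with mirror padding
fft_filter <- function(x, fs, gain_fun) {
  n <- length(x)
  if (n < 8) {
    stop_respyre("Signal too short for stable filtering.", "respyre_signal_error")
  }
  pad <- min(n, 8192L)
  left <- rev(x[seq_len(pad)])
  right <- rev(x[(n - pad + 1):n])
  xe <- c(left, x, right)
  m <- stats::nextn(length(xe), factors = c(2, 3, 5))
  if (m > length(xe)) xe <- c(xe, rep(xe[length(xe)], m - length(xe)))
  f <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) * fs / m
  g <- gain_fun(abs(f))
  y <- Re(stats::fft(stats::fft(xe) * g, inverse = TRUE)) / m
  y[(pad + 1):(pad + n)]
}

#' @describeIn preprocess Remove DC and very-low-frequency drift with a
#'   high-pass whose -3 dB cutoff is `cutoff_bpm` breaths/min (default 4).
#' @param cutoff_bpm High-pass cutoff in breaths/min.
#' @export
highpass_vlf <- function(signal, cutoff_bpm = 4) {
  w <- as_wave(signal)
  fc <- cutoff_bpm / 60
  if (wave_fs(w) <= 2 * fc) {
    stop_respyre("Sampling rate must exceed twice the cutoff.", "respyre_signal_error")
  }
  wave_update(w, fft_filter(w$amplitude, wave_fs(w),
                            function(f) butter_gain2(f, lo = fc)))
}

#' @describeIn preprocess Band-pass to the respiratory band, -3 dB edges
#'   `band_bpm` breaths/min (default 4 and 60).
#' @param band_bpm Length-2 band edges in breaths/min.
#' @export
bandpass_resp <- function(signal, band_bpm = c(4, 60)) {
  w <- as_wave(signal)
  lo <- band_bpm[1] / 60; hi <- band_bpm[2] / 60
  if (wave_fs(w) <= 2 * hi) {
    stop_respyre("Sampling rate must exceed twice the upper band edge.",
                 "respyre_signal_error")
  }
  wave_update(w, fft_filter(w$amplitude, wave_fs(w),
                            function(f) butter_gain2(f, lo = lo, hi = hi)))
}

#' @describeIn preprocess Remove high-frequency noise from the PPG with a
#'   low-pass whose -3 dB cutoff is `cutoff_hz` (default 35 Hz).
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @export
lowpass_ppg <- function(signal, cutoff_hz = 35) {
  w <- as_wave(signal)
  if (wave_fs(w) <= 2 * cutoff_hz) {
    stop_respyre("Sampling rate must exceed twice the low-pass cutoff.",
                 "respyre_signal_error")
  }
  wave_update(w, fft_filter(w$amplitude, wave_fs(w),
                            function(f) butter_gain2(f, hi = cutoff_hz)))
}

#' Resample a waveform to a uniform target rate
#'
#' Downsampling applies an anti-alias low-pass (order 8, cutoff at 45% of the
#' target rate) before linear interpolation onto the target grid. Output
#' length is `round(n * target_rate / fs)`, preserving duration to within one
#' sample.
#'
#' @param signal A `resp_wave` or coercible data frame.
#' @param target_rate Target sampling rate, Hz (> 0).
#' @return A `resp_wave` at `target_rate`.
#' @export
resample_uniform <- function(signal, target_rate) {
  w <- as_wave(signal)
  check_number(target_rate, "target_rate", min = .Machine$double.eps)
  fs <- wave_fs(w)
  if (abs(target_rate - fs) < 1e-12) return(w)
  x <- w$amplitude
  if (target_rate < fs) {
    x <- fft_filter(x, fs, function(f) butter_gain2(f, hi = 0.45 * target_rate, order = 8))
  }
  n_out <- round(nrow(w) * target_rate / fs)
  t_in <- (seq_along(x) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / target_rate
  t_out <- pmin(t_out, t_in[length(t_in)])
  y <- stats::approx(t_in, x, xout = t_out)$y
  wave_signal(y, fs = target_rate, t0 = wave_t0(w),
              provenance = attr(w, "provenance"))
}

#' Z-score a signal and clip to two standard deviations
#'
#' Centres and scales by the population mean and standard deviation of the
#' whole record, then hard-clips all samples into `[-2, 2]`. This removes
#' between-subject baseline differences and bounds the dynamic range of the
#' respiratory signal fed to the sequence classifier.
#'
#' @param signal A `resp_wave` or coercible data frame.
#' @param clip Clip bound in standard deviations (default 2).
#' @return A `resp_wave`, mean approximately 0, samples in `[-clip, clip]`.
#' @export
zscore_clip <- function(signal, clip = 2) {
  w <- as_wave(signal)
  x <- w$amplitude
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s <= 0) {
    stop_respyre("Signal is constant; z-scoring is undefined.", "respyre_signal_error")
  }
  z <- (x - m) / s
  wave_update(w, pmin(pmax(z, -clip), clip))
}

#' Cut a signal into fixed-length windows
#'
#' Windows are taken left to right; a trailing partial window is dropped.
#' Intervals are half-open `[start_s, end_s)` and non-overlapping when
#' `stride == window_samples`.
#'
#' @param signal A `resp_wave` or coercible data frame.
#' @param window_samples Window length in samples.
#' @param stride Stride in samples (default `window_samples`).
#' @return A tibble with `window`, `start_s`, `end_s`, and a list-column
#'   `samples`; zero rows if the signal is shorter than one window.
#' @export
segment_windows <- function(signal, window_samples, stride = window_samples) {
  w <- as_wave(signal)
  check_number(window_samples, "window_samples", min = 1)
  check_number(stride, "stride", min = 1)
  n <- nrow(w); fs <- wave_fs(w); t0 <- wave_t0(w)
  starts <- seq(1L, by = as.integer(stride), length.out =
                  max(0L, (n - as.integer(window_samples)) %/% as.integer(stride) + 1L))
  if (window_samples > n) starts <- integer(0)
  tibble(
    window = seq_along(starts),
    start_s = t0 + (starts - 1) / fs,
    end_s = t0 + (starts - 1 + window_samples) / fs,
    samples = purrr::map(starts, function(s) w$amplitude[s:(s + window_samples - 1)])
  )
}
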