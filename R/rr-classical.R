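#' @name rr_estimators
#' @title Windowed respiratory-rate estimators
#'
#' @description
#' Each estimator takes a uniformly sampled respiratory surrogate signal and a
#' half-open analysis window `[start_s, end_s)` and returns a one-row tibble:
#' `method`, `start_s`, `end_s`, `rr` (breaths/min, `NA` when invalid),
#' `valid`. An estimate is valid only when it lies in the plausible band of
#' 4-60 breaths/min.
#'
#' @param resp A respiratory `resp_wave` (or coercible data frame),
#'   approximately zero-mean within the window.
#' @param window Length-2 numeric `c(start_s, end_s)`; `NULL` uses the whole
#'   signal.
NULL

rr_result <- function(method, window, rr, valid, extra = list()) {
  out <- tibble(method = method, start_s = window[1], end_s = window[2],
                rr = ifelse(valid, rr, NA_real_), valid = valid)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# samples of a wave within a half-open window [start, end)
wave_window <- function(w, window) {
  fs <- wave_fs(w); t0 <- wave_t0(w); n <- nrow(w)
  if (is.null(window)) window <- c(t0, t0 + n / fs)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop_respyre("`window` must be c(start_s, end_s) with end > start.",
                 "respyre_config_error")
  }
  if (window[1] < t0 - 1e-9 || window[2] > t0 + n / fs + 1e-9) {
    stop_respyre("Window lies outside the signal extent.", "respyre_signal_error")
  }
  i0 <- max(1L, floor((window[1] - t0) * fs + 1e-9) + 1L)
  i1 <- min(n, ceiling((window[2] - t0) * fs - 1e-9))
  list(x = w$amplitude[i0:i1], window = window, fs = fs)
}

#' @describeIn rr_estimators Time-domain: breaths are positive-gradient zero
#'   crossings; RR is 60 times their count over the window duration.
#' @export
rr_zero_crossing <- function(resp, window = NULL) {
  w <- as_wave(resp)
  s <- wave_window(w, window)
  x <- s$x
  cross <- sum(x[-length(x)] <= 0 & x[-1] > 0)
  rr <- 60 * cross / (s$window[2] - s$window[1])
  rr_result("zero_crossing", s$window, rr, valid = cross > 0 && rr >= 4 && rr <= 60)
}

#' @describeIn rr_estimators Time-domain: breaths detected as peaks whose
#'   rise from the preceding trough exceeds `excursion_frac` of the window's
#'   interquartile amplitude range.
#' @param excursion_frac Minimum peak-to-trough excursion as a fraction of
#'   the window IQR (default 0.2); suppresses noise ripples.
#' @export
rr_trough_peak <- function(resp, window = NULL, excursion_frac = 0.2) {
  w <- as_wave(resp)
  s <- wave_window(w, window)
  x <- s$x
  thr <- excursion_frac * stats::IQR(x)
  d <- diff(x)
  sg <- sign(d)
  for (i in seq_along(sg)) if (sg[i] == 0 && i > 1) sg[i] <- sg[i - 1]
  turns <- which(diff(sg) != 0) + 1L
  breaths <- 0L
  if (length(turns)) {
    is_pk <- sg[turns] < 0            # slope after a local max is negative
    last_trough_val <- x[1]
    for (k in seq_along(turns)) {
      v <- x[turns[k]]
      if (is_pk[k]) {
        if (v - last_trough_val > thr && thr > 0) breaths <- breaths + 1L
      } else {
        last_trough_val <- v
      }
    }
  }
  rr <- 60 * breaths / (s$window[2] - s$window[1])
  rr_result("trough_peak", s$window, rr, valid = breaths > 0 && rr >= 4 && rr <= 60)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-tapered segments (up to `seg_s`
#' seconds, 50% overlap), each demeaned, zero-padded so the frequency grid is
#' at most `df_bpm` breaths/min wide.
#'
#' @param x Numeric samples.
#' @param fs Sampling rate, Hz.
#' @param seg_s Maximum segment length, seconds (default 32).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param df_bpm Maximum frequency-grid spacing in breaths/min (default 0.5).
#' @return A tibble with `frequency` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, seg_s = 32, overlap = 0.5, df_bpm = 0.5) {
  n <- length(x)
  seg <- min(n, round(seg_s * fs))
  if (seg < 8) stop_respyre("Too few samples for a spectrum.", "respyre_signal_error")
  step <- max(1L, round(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg) - 1) / (seg - 1))  # Hann
  nfft <- 2^ceiling(log2(max(seg, fs / (df_bpm / 60))))
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg_x <- x[s0:(s0 + seg - 1)]
    seg_x <- (seg_x - mean(seg_x)) * win
    X <- stats::fft(c(seg_x, numeric(nfft - seg)))
    p <- Mod(X[seq_len(nfft %/% 2 + 1)])^2 / (fs * sum(win^2))
    acc <- acc + p
  }
  tibble(frequency = (0:(nfft %/% 2)) * fs / nfft, power = acc / length(starts))
}

#' @describeIn rr_estimators Frequency-domain: RR is 60 times the frequency
#'   of the largest Welch-periodogram peak within the respiratory band.
#'   Windows shorter than two cycles at the lower band edge are allowed but
#'   low-resolution; a spectral-flatness diagnostic above
#'   `flatness_threshold` marks the estimate `low_confidence`.
#' @param band_bpm Search band in breaths/min (default 4 to 60).
#' @param flatness_threshold Spectral flatness (geometric over arithmetic
#'   mean of in-band power) above which the estimate is flagged
#'   low-confidence (default 0.5).
#' @export
rr_spectral <- function(resp, window = NULL, band_bpm = c(4, 60),
                        flatness_threshold = 0.5) {
  w <- as_wave(resp)
  s <- wave_window(w, window)
  spec <- welch_psd(s$x, s$fs)
  band <- spec$frequency >= band_bpm[1] / 60 & spec$frequency <= band_bpm[2] / 60
  p <- spec$power[band]; f <- spec$frequency[band]
  if (!length(p) || max(p) <= 0) {
    return(rr_result("spectral", s$window, NA_real_, valid = FALSE,
                     extra = list(low_confidence = TRUE)))
  }
  rr <- 60 * f[which.max(p)]          # ties break to the lowest frequency
  eps <- 1e-15 * max(p)
  flat <- exp(mean(log(p + eps))) / mean(p + eps)
  rr_result("spectral", s$window, rr, valid = rr >= 4 && rr <= 60,
            extra = list(low_confidence = flat > flatness_threshold))
}

#' Smart fusion of the three modulation estimates
#'
#' Combines the baseline-wander, amplitude-modulation and
#' frequency-modulation RR estimates of one window: when their sample
#' standard deviation is below `sd_threshold` (4 breaths/min) the fused RR is
#' their mean, otherwise the fusion abstains (no RR is produced). Invalid
#' inputs propagate to an abstention.
#'
#' @param estimates A tibble of exactly three estimator rows (as returned by
#'   the `rr_*` estimators), or a numeric vector of three RR values.
#' @param sd_threshold Agreement threshold in breaths/min (default 4).
#' @return A one-row estimate tibble with an `sd` column.
#' @export
#' @examples
#' smart_fusion(c(10, 11, 12))  # fused to 11
#' smart_fusion(c(5, 15, 25))   # abstains (SD = 10)
smart_fusion <- function(estimates, sd_threshold = 4) {
  if (is.numeric(estimates)) {
    estimates <- tibble(rr = as.numeric(estimates),
                        valid = is.finite(estimates),
                        start_s = NA_real_, end_s = NA_real_)
  }
  if (nrow(estimates) != 3) {
    stop_respyre("Smart fusion requires exactly three estimates (BW, AM, FM).",
                 "respyre_config_error")
  }
  win <- c(estimates$start_s[1], estimates$end_s[1])
  if (!all(estimates$valid)) {
    return(rr_result("smart_fusion", win, NA_real_, valid = FALSE,
                     extra = list(sd = NA_real_)))
  }
  s <- stats::sd(estimates$rr)
  if (s < sd_threshold) {
    rr_result("smart_fusion", win, mean(estimates$rr), valid = TRUE,
              extra = list(sd = s))
  } else {
    rr_result("smart_fusion", win, NA_real_, valid = FALSE,
              extra = list(sd = s))
  }
}

#' Spectral peak-conditioned averaging
#'
#' Fuses the Welch spectra of the modulation signals: each spectrum is
#' normalised to unit total in-band power and included only when the fraction
#' of its power within `halfwidth_hz` of its own maximum reaches
#' `inclusion_threshold`; RR is 60 times the argmax frequency of the mean of
#' the included spectra. When every spectrum is too diffuse the fusion
#' abstains.
#'
#' @param spectra A tibble with columns `series`, `frequency`, `power`
#'   (stacked spectra on a common grid), or a list of `frequency`/`power`
#'   tibbles such as [welch_psd()] returns.
#' @param band_bpm In-band range in breaths/min (default 4 to 60).
#' @param inclusion_threshold Minimum concentrated-power fraction (default
#'   0.33).
#' @param halfwidth_hz Half-width of the concentration band around each
#'   spectrum's maximum, Hz (default 0.1).
#' @return A one-row estimate tibble with an `n_included` column.
#' @export
spectral_peak_average <- function(spectra, band_bpm = c(4, 60),
                                  inclusion_threshold = 0.33,
                                  halfwidth_hz = 0.1) {
  if (is.data.frame(spectra)) {
    if (!all(c("series", "frequency", "power") %in% names(spectra))) {
      stop_respyre("`spectra` must have series/frequency/power columns.",
                   "respyre_format_error")
    }
    lst <- split(spectra[c("frequency", "power")], spectra$series)
  } else {
    lst <- spectra
  }
  if (!length(lst)) stop_respyre("No spectra supplied.", "respyre_config_error")
  grid <- lst[[1]]$frequency
  for (sp in lst) {
    if (length(sp$frequency) != length(grid) ||
        max(abs(sp$frequency - grid)) > 1e-9) {
      stop_respyre("Spectra are not on a common frequency grid.",
                   "respyre_format_error")
    }
  }
  band <- grid >= band_bpm[1] / 60 & grid <= band_bpm[2] / 60
  fb <- grid[band]
  norm <- purrr::map(lst, function(sp) {
    p <- sp$power[band]
    tot <- sum(p)
    if (tot <= 0) return(NULL)
    p / tot
  })
  keep <- purrr::map_lgl(norm, function(p) {
    if (is.null(p)) return(FALSE)
    fmax <- fb[which.max(p)]
    sum(p[abs(fb - fmax) <= halfwidth_hz]) >= inclusion_threshold
  })
  if (!any(keep)) {
    return(rr_result("spectral_peak_average", c(NA_real_, NA_real_), NA_real_,
                     valid = FALSE, extra = list(n_included = 0L)))
  }
  mean_spec <- Reduce(`+`, norm[keep]) / sum(keep)
  rr <- 60 * fb[which.max(mean_spec)]
  rr_result("spectral_peak_average", c(NA_real_, NA_real_), rr,
            valid = rr >= 4 && rr <= 60,
            extra = list(n_included = sum(keep)))
}

#' Temporal fusion of successive estimates from one subject
#'
#' `temporal_fusion()` returns the smoothed estimate at the end of a history:
#' the median of the most recent `k` valid estimates (fewer are allowed near
#' the start; with no valid estimate in the history it abstains).
#' `temporal_smooth()` applies the same causal rule at every position of an
#' estimate sequence, adding `rr_smooth`/`valid_smooth` columns.
#'
#' @param history A tibble of estimates ordered in time (columns `rr`,
#'   `valid`), or a numeric vector (with `NA` marking invalid windows).
#' @param k Number of recent valid estimates in the median (default 3).
#' @return A one-row estimate tibble (`temporal_fusion`) or the input with
#'   smoothing columns added (`temporal_smooth`).
#' @export
temporal_fusion <- function(history, k = 3) {
  if (is.numeric(history)) {
    history <- tibble(rr = as.numeric(history), valid = is.finite(history),
                      start_s = NA_real_, end_s = NA_real_)
  }
  if (nrow(history) == 0) {
    stop_respyre("Temporal fusion requires a non-empty history.", "respyre_config_error")
  }
  vals <- history$rr[history$valid]
  win <- c(history$start_s[nrow(history)], history$end_s[nrow(history)])
  if (!length(vals)) {
    return(rr_result("temporal_fusion", win, NA_real_, valid = FALSE))
  }
  rr_result("temporal_fusion", win, stats::median(tail(vals, k)), valid = TRUE)
}

#' @rdname temporal_fusion
#' @param estimates A tibble of estimates ordered in time.
#' @export
temporal_smooth <- function(estimates, k = 3) {
  rr <- estimates$rr; valid <- estimates$valid
  out_rr <- rep(NA_real_, length(rr)); out_valid <- logical(length(rr))
  for (i in seq_along(rr)) {
    vals <- rr[seq_len(i)][valid[seq_len(i)]]
    if (length(vals)) {
      out_rr[i] <- stats::median(tail(vals, k))
      out_valid[i] <- TRUE
    }
  }
  dplyr::mutate(estimates, rr_smooth = out_rr, valid_smooth = out_valid)
}

#' Plot a sequence of RR estimates
#'
#' @param object A tibble of estimates with `start_s`, `rr` and (optionally)
#'   `rr_smooth` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rr_estimates <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$start_s, y = .data$rr)) +
    geom_point(na.rm = TRUE) +
    labs(x = "window start (s)", y = "RR (breaths/min)") +
    theme_minimal()
  if ("rr_smooth" %in% names(object)) {
    p <- p + geom_line(aes(y = .data$rr_smooth), colour = "steelblue", na.rm = TRUE)
  }
  p
}
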