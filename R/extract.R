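#' Segment a PPG waveform into cardiac pulses
#'
#' Incremental line-segment merging: the waveform is split at its turning
#' points into monotone line segments; candidate up-slopes (trough-to-peak
#' rises) are accepted as systolic rises only when their amplitude reaches
#' `min_upstroke_frac` of the running median of accepted rise amplitudes.
#' Smaller up-slopes — dicrotic-notch bumps and noise wiggles — are thereby
#' merged into the enclosing pulse. Beats whose amplitude or inter-beat
#' interval deviates more than `flag_factor`-fold from the running median are
#' artifact-flagged (and excluded from feature series downstream).
#'
#' @param signal A low-pass-filtered PPG `resp_wave` (or coercible data
#'   frame), at least 2 s long.
#' @param min_upstroke_frac Acceptance threshold as a fraction of the running
#'   median up-slope amplitude (default 0.5).
#' @param flag_factor Artifact flag threshold: deviation factor versus the
#'   running median (default 2.5).
#' @param flag_window Beats in the running-median window (default 11).
#' @return A tibble with one row per detected pulse: `beat`, `onset_idx`,
#'   `trough_idx`, `peak_idx` (1-based sample indices), `trough_s`, `peak_s`,
#'   `trough_amp`, `peak_amp`, `interval_s` (peak-to-peak, `NA` for the first
#'   beat), `artifact`. Zero rows (with a warning) when no pulses are found.
#' @export
segment_pulses <- function(signal, min_upstroke_frac = 0.5, flag_factor = 2.5,
                           flag_window = 11) {
  w <- as_wave(signal)
  fs <- wave_fs(w); t0 <- wave_t0(w)
  x <- w$amplitude
  n <- length(x)
  empty <- tibble(beat = integer(), onset_idx = integer(), trough_idx = integer(),
                  peak_idx = integer(), trough_s = numeric(), peak_s = numeric(),
                  trough_amp = numeric(), peak_amp = numeric(),
                  interval_s = numeric(), artifact = logical())
  if (n < 2 * fs || diff(range(x)) == 0) {
    rlang::warn("No pulses found in signal.")
    return(empty)
  }

  # turning points: sign changes of the first difference (plateaus carried)
  d <- diff(x)
  s <- sign(d)
  if (any(s == 0)) {
    nz <- s != 0
    if (!any(nz)) {
      rlang::warn("No pulses found in signal.")
      return(empty)
    }
    fill <- cumsum(nz)
    fill[fill == 0] <- 1L
    s <- s[which(nz)][fill]
  }
  turns <- which(diff(s) != 0) + 1L
  ext_idx <- c(1L, turns, n)
  ext_val <- x[ext_idx]
  is_max <- c(FALSE, s[turns] < 0, s[n - 1] > 0)   # slope after a max is negative
  is_max[1] <- !is_max[2]

  # incremental merge: oscillations whose excursion is small relative to the
  # pulse-amplitude scale are wiggles (noise, notch ripple); removing the
  # extremum pair merges the adjacent monotone segments into one line
  scale <- stats::quantile(abs(diff(ext_val)), 0.95, names = FALSE)
  if (!is.finite(scale) || scale <= 0) {
    rlang::warn("No pulses found in signal.")
    return(empty)
  }
  h <- 0.2 * scale
  m <- length(ext_val)
  st <- integer(m); top <- 0L
  for (e in seq_len(m)) {
    top <- top + 1L
    st[top] <- e
    while (top >= 2L && abs(ext_val[st[top]] - ext_val[st[top - 1L]]) < h) {
      top <- top - 2L               # pop the wiggle pair, merging its neighbours
    }
  }
  keep <- st[seq_len(top)]
  ext_idx <- ext_idx[keep]; ext_val <- ext_val[keep]; is_max <- is_max[keep]

  # candidate up-slopes: (min, following max)
  ks <- which(!is_max)
  ks <- ks[ks + 1 <= length(ext_idx)]
  if (!length(ks)) {
    rlang::warn("No pulses found in signal.")
    return(empty)
  }
  cand <- cbind(i = ext_idx[ks], j = ext_idx[ks + 1])
  amps <- x[cand[, "j"]] - x[cand[, "i"]]
  warm <- stats::quantile(amps[amps > 0], 0.75, names = FALSE)
  if (!is.finite(warm) || warm <= 0) {
    rlang::warn("No pulses found in signal.")
    return(empty)
  }

  acc_i <- integer(0); acc_j <- integer(0); acc_amp <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    a <- amps[k]
    med <- if (length(acc_amp) >= 3) {
      stats::median(tail(acc_amp, flag_window))
    } else warm
    if (a < min_upstroke_frac * med) next
    if (length(acc_j)) {
      med_int <- if (length(acc_j) >= 3) {
        stats::median(diff(tail(acc_j, flag_window)))
      } else 0.3 * fs
      if (cand[k, "j"] - tail(acc_j, 1) < 0.3 * med_int) {
        # refractory: two peaks too close -- keep the larger rise
        if (a > tail(acc_amp, 1)) {
          acc_i <- head(acc_i, -1); acc_j <- head(acc_j, -1)
          acc_amp <- head(acc_amp, -1)
        } else next
      }
    }
    acc_i <- c(acc_i, cand[k, "i"]); acc_j <- c(acc_j, cand[k, "j"])
    acc_amp <- c(acc_amp, a)
  }
  if (!length(acc_j)) {
    rlang::warn("No pulses found in signal.")
    return(empty)
  }

  beats <- tibble(
    beat = seq_along(acc_j),
    onset_idx = as.integer(acc_i),
    trough_idx = as.integer(acc_i),
    peak_idx = as.integer(acc_j),
    trough_s = t0 + (acc_i - 1) / fs,
    peak_s = t0 + (acc_j - 1) / fs,
    trough_amp = x[acc_i],
    peak_amp = x[acc_j],
    interval_s = c(NA_real_, diff(t0 + (acc_j - 1) / fs))
  )

  # artifact flags: amplitude or interval > flag_factor-fold off the running median
  run_med <- function(v) {
    v2 <- v; v2[is.na(v2)] <- stats::median(v, na.rm = TRUE)
    if (length(v2) >= flag_window) {
      stats::runmed(v2, k = flag_window, endrule = "median")
    } else rep(stats::median(v2), length(v2))
  }
  amp <- beats$peak_amp - beats$trough_amp
  med_amp <- run_med(amp)
  med_int <- run_med(beats$interval_s)
  flag_amp <- amp > flag_factor * med_amp | amp < med_amp / flag_factor
  flag_int <- !is.na(beats$interval_s) &
    (beats$interval_s > flag_factor * med_int | beats$interval_s < med_int / flag_factor)
  beats$artifact <- flag_amp | flag_int
  attr(beats, "fs") <- fs
  beats
}

#' Beat-by-beat feature series for respiratory extraction
#'
#' Converts pulse annotations into an irregularly sampled feature series whose
#' slow variation tracks respiration. Artifact-flagged beats are excluded.
#'
#' Feature kinds:
#' * `peak_amplitude`, `am` — pulse amplitude (peak minus preceding trough),
#'   at the peak time; amplitude modulation.
#' * `fm` — beat-to-beat (peak-to-peak) interval in seconds, at the later
#'   beat's time; frequency modulation.
#' * `bw` — mean of peak and trough amplitude, at the peak time; baseline
#'   wander.
#' * `trough_mean` — mean of consecutive trough amplitudes, at the midpoint
#'   time.
#'
#' @param beats Pulse annotations from [segment_pulses()].
#' @param kind Feature kind (see above).
#' @return A tibble of class `feature_series` with columns `time`, `value`;
#'   the kind is stored in the `"kind"` attribute.
#' @export
beat_features <- function(beats, kind = c("am", "fm", "bw", "peak_amplitude",
                                          "trough_mean")) {
  kind <- match.arg(kind)
  b <- dplyr::filter(beats, !.data$artifact)
  if (nrow(b) < 2) {
    stop_respyre("At least two unflagged beats are required.", "respyre_data_error")
  }
  out <- switch(
    kind,
    am = ,
    peak_amplitude = tibble(time = b$peak_s, value = b$peak_amp - b$trough_amp),
    bw = tibble(time = b$peak_s, value = (b$peak_amp + b$trough_amp) / 2),
    fm = tibble(time = b$peak_s[-1], value = diff(b$peak_s)),
    trough_mean = tibble(
      time = (b$trough_s[-nrow(b)] + b$trough_s[-1]) / 2,
      value = (b$trough_amp[-nrow(b)] + b$trough_amp[-1]) / 2
    )
  )
  out <- dplyr::filter(out, !duplicated(.data$time))
  attr(out, "kind") <- kind
  class(out) <- c("feature_series", class(out))
  out
}

#' Resample an irregular feature series to a uniform respiratory signal
#'
#' Interpolates the beat-feature series onto a uniform grid from the first to
#' the last feature time, then (by default) band-passes the result to the
#' respiratory band of 4-60 breaths/min and removes its mean.
#'
#' @param series A `feature_series` tibble (`time`, `value`) or any data
#'   frame with those columns.
#' @param method `"linear"` (straight lines between points),
#'   `"cubic_spline"` (interpolating cubic spline), or `"berger"` (local
#'   triangular-weighted averaging of the event values; approximate).
#' @param target_rate Surrogate sampling rate, Hz (default 4; ample for
#'   respiration at or below 1 Hz).
#' @param bandpass Apply the respiratory band-pass after interpolation
#'   (default `TRUE`).
#' @param band_bpm Band edges in breaths/min for the optional band-pass.
#' @return A `resp_wave` at `target_rate` whose provenance records the
#'   feature kind.
#' @export
resample_features <- function(series, method = c("linear", "cubic_spline", "berger"),
                              target_rate = 4, bandpass = TRUE,
                              band_bpm = c(4, 60)) {
  method <- match.arg(method)
  check_number(target_rate, "target_rate", min = .Machine$double.eps)
  if (!all(c("time", "value") %in% names(series))) {
    stop_respyre("`series` must have `time` and `value` columns.", "respyre_format_error")
  }
  tt <- series$time; vv <- series$value
  if (length(tt) < 2) {
    stop_respyre("At least two feature points are required.", "respyre_data_error")
  }
  grid <- seq(tt[1], tt[length(tt)], by = 1 / target_rate)
  y <- switch(
    method,
    linear = stats::approx(tt, vv, xout = grid)$y,
    cubic_spline = stats::spline(tt, vv, xout = grid)$y,
    berger = {
      h <- 2 / target_rate
      lin <- stats::approx(tt, vv, xout = grid)$y
      vapply(seq_along(grid), function(g) {
        wgt <- pmax(0, 1 - abs(tt - grid[g]) / h)
        if (sum(wgt) > 0) sum(wgt * vv) / sum(wgt) else lin[g]
      }, numeric(1))
    }
  )
  out <- wave_signal(y, fs = target_rate, t0 = grid[1],
                     provenance = attr(series, "kind") %||% "feature")
  if (bandpass) {
    out <- bandpass_resp(out, band_bpm = band_bpm)
    out <- wave_update(out, out$amplitude - mean(out$amplitude))
  }
  out
}

#' Filter-based respiratory signal extraction
#'
#' Band-passes the PPG itself to the respiratory band and downsamples to the
#' surrogate rate — no pulse segmentation involved. This captures mainly the
#' baseline-wander route.
#'
#' @param signal Raw or low-passed PPG (`resp_wave` or coercible data frame).
#' @param target_rate Surrogate sampling rate, Hz (default 4).
#' @param band_bpm Band edges in breaths/min (default 4 and 60).
#' @return A `resp_wave` with provenance `"filter_based"`.
#' @export
extract_filter_based <- function(signal, target_rate = 4, band_bpm = c(4, 60)) {
  w <- bandpass_resp(as_wave(signal), band_bpm = band_bpm)
  out <- resample_uniform(w, target_rate)
  attr(out, "provenance") <- "filter_based"
  out
}
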