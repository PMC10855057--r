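#' Configuration for the synthetic respiratory-modulated PPG generator
#'
#' The generator realises the three respiratory modulation routes of the PPG:
#' baseline wander (BW, an additive sinusoid at the respiratory frequency),
#' amplitude modulation (AM, the pulse height varies with respiratory phase),
#' and frequency modulation (FM, the inter-beat interval varies with
#' respiratory phase). Each pulse is the sum of two Gaussians: the systolic
#' peak and a smaller, delayed dicrotic-notch bump.
#'
#' @param duration_s Signal duration, seconds (> 0).
#' @param sampling_rate Sampling rate, Hz (default 125, the bedside-monitor
#'   convention of the public PPG benchmarks).
#' @param heart_rate Mean heart rate, beats/min.
#' @param resp_rate Respiratory rate, breaths/min: a scalar in `[4, 60]` or a
#'   piecewise-constant schedule `data.frame(start_s, rate)`.
#' @param bw_depth,am_depth,fm_depth Modulation depths, dimensionless
#'   fractions in `[0, 1]`.
#' @param notch_amplitude Dicrotic-notch height as a fraction of pulse
#'   amplitude.
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   units of the (unit) pulse amplitude.
#' @param artifacts List of artifact entries, each a list with `start_s`,
#'   `duration_s`, `kind` (`"spike"`, `"step"` or `"dropout"`) and `magnitude`.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(duration_s, sampling_rate = 125, heart_rate = 75,
                         resp_rate = 15, bw_depth = 0.1, am_depth = 0.1,
                         fm_depth = 0.1, notch_amplitude = 0.2, noise_sd = 0,
                         artifacts = list(), seed = 1L) {
  check_number(duration_s, "duration_s", min = .Machine$double.eps)
  check_number(sampling_rate, "sampling_rate", min = 1)
  check_number(heart_rate, "heart_rate", min = 20, max = 240)
  if (is.data.frame(resp_rate)) {
    if (!all(c("start_s", "rate") %in% names(resp_rate)) || nrow(resp_rate) < 1) {
      stop_respyre("A respiratory-rate schedule needs `start_s` and `rate` columns.",
                   "respyre_config_error")
    }
    if (is.unsorted(resp_rate$start_s, strictly = TRUE)) {
      stop_respyre("Schedule `start_s` must be strictly increasing.", "respyre_config_error")
    }
    if (any(resp_rate$rate < 4 | resp_rate$rate > 60)) {
      stop_respyre("Respiratory rates must lie in [4, 60] breaths/min.", "respyre_config_error")
    }
  } else {
    check_number(resp_rate, "resp_rate", min = 4, max = 60)
  }
  check_number(bw_depth, "bw_depth", min = 0, max = 1)
  check_number(am_depth, "am_depth", min = 0, max = 1)
  check_number(fm_depth, "fm_depth", min = 0, max = 1)
  check_number(notch_amplitude, "notch_amplitude", min = 0, max = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(seed, "seed")
  structure(
    list(duration_s = duration_s, sampling_rate = sampling_rate,
         heart_rate = heart_rate, resp_rate = resp_rate, bw_depth = bw_depth,
         am_depth = am_depth, fm_depth = fm_depth,
         notch_amplitude = notch_amplitude, noise_sd = noise_sd,
         artifacts = artifacts, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# cumulative respiratory phase (radians) at times t for a config
resp_phase_fun <- function(config) {
  rr <- config$resp_rate
  if (!is.data.frame(rr)) {
    omega <- 2 * pi * rr / 60
    return(function(t) omega * t)
  }
  starts <- c(rr$start_s, Inf)
  rates <- rr$rate
  # phase accumulated at each breakpoint
  seg_len <- diff(pmin(starts, config$duration_s))
  phase0 <- c(0, cumsum(2 * pi * rates / 60 * pmax(seg_len, 0)))
  function(t) {
    idx <- findInterval(t, rr$start_s, rightmost.closed = FALSE)
    idx[idx < 1] <- 1L
    phase0[idx] + 2 * pi * rates[idx] / 60 * (t - rr$start_s[idx])
  }
}

#' Generate a synthetic respiratory-modulated PPG signal
#'
#' Builds a pulsatile carrier (one two-Gaussian pulse per cardiac cycle, with
#' a dicrotic-notch bump), modulates it by respiration on the three routes
#' (BW, AM, FM), adds white Gaussian noise, injects the configured artifacts,
#' and returns ground-truth breath annotations. Breath onsets are the
#' positive-going zero crossings of the respiratory phase oscillator.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_ppg` with elements `signal` (a
#'   [wave_signal()] tibble), `breaths` (tibble with column `onset_s`), and
#'   `config`.
#' @export
#' @examples
#' sim <- generate_ppg(synth_config(duration_s = 60, heart_rate = 75,
#'                                  resp_rate = 15, seed = 1))
#' nrow(sim$breaths)  # 15 breaths in one minute
generate_ppg <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop_respyre("`config` must be created with synth_config().", "respyre_config_error")
  }
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- resp_phase_fun(config)

  signal <- with_seed_(config$seed, {
    # FM: successive inter-beat intervals scaled by (1 + fm * sin(resp phase))
    t0_beat <- 60 / config$heart_rate
    beats <- numeric(0)
    tk <- 0
    while (tk < config$duration_s + t0_beat) {
      beats <- c(beats, tk)
      tk <- tk + t0_beat * (1 + config$fm_depth * sin(phase(tk)))
    }
    periods <- c(diff(beats), t0_beat)
    x <- numeric(n)
    for (k in seq_along(beats)) {
      tk <- beats[k]
      per <- periods[k]
      amp <- 1 + config$am_depth * sin(phase(tk))
      mu1 <- tk + 0.30 * per; s1 <- 0.10 * per
      mu2 <- tk + 0.62 * per; s2 <- 0.12 * per
      lo <- max(1L, floor((tk - 0.2 * per) * fs) + 1L)
      hi <- min(n, ceiling((tk + 1.2 * per) * fs) + 1L)
      if (lo > hi) next
      tt <- t[lo:hi]
      x[lo:hi] <- x[lo:hi] +
        amp * (exp(-(tt - mu1)^2 / (2 * s1^2)) +
               config$notch_amplitude * exp(-(tt - mu2)^2 / (2 * s2^2)))
    }
    x <- x + config$bw_depth * sin(phase(t))
    if (config$noise_sd > 0) x <- x + rnorm(n, sd = config$noise_sd)
    x
  })

  w <- wave_signal(signal, fs = fs, provenance = "synthetic_ppg")
  for (a in config$artifacts) {
    w <- inject_artifact(w, start_s = a$start_s, duration_s = a$duration_s,
                         kind = a$kind, magnitude = a$magnitude %||% 1)
  }

  # breath onsets: phase = 2*pi*k, k = 0, 1, ...
  total_phase <- phase(config$duration_s)
  ks <- 0:floor(total_phase / (2 * pi))
  if (is.data.frame(config$resp_rate)) {
    grid_t <- seq(0, config$duration_s, length.out = 4096)
    onsets <- stats::approx(phase(grid_t), grid_t, xout = 2 * pi * ks)$y
  } else {
    onsets <- 60 * ks / config$resp_rate
  }
  onsets <- onsets[is.finite(onsets) & onsets < config$duration_s]

  structure(
    list(signal = w,
         breaths = tibble(onset_s = onsets),
         config = config),
    class = "synthetic_ppg"
  )
}

#' @export
print.synthetic_ppg <- function(x, ...) {
  cat(sprintf("<synthetic_ppg> %.0f s @ %g Hz, HR %g bpm, %d breath onsets\n",
              x$config$duration_s, x$config$sampling_rate,
              x$config$heart_rate, nrow(x$breaths)))
  invisible(x)
}

#' Superimpose an artifact on a waveform
#'
#' Emulates the motion/light/noise disturbances that corrupt real PPG
#' recordings: a half-sine `spike`, an additive `step` over the interval, or a
#' `dropout` that freezes the signal at its value at the interval start.
#' Samples outside the interval are unchanged.
#'
#' @param signal A `resp_wave` (or coercible data frame).
#' @param start_s,duration_s Artifact interval, seconds (half-open, must lie
#'   within the signal extent).
#' @param kind `"spike"`, `"step"` or `"dropout"`.
#' @param magnitude Artifact height in amplitude units (ignored for
#'   `dropout`).
#' @return A `resp_wave` with the artifact applied.
#' @export
inject_artifact <- function(signal, start_s, duration_s,
                            kind = c("spike", "step", "dropout"),
                            magnitude = 1) {
  w <- as_wave(signal)
  kind <- match.arg(kind)
  check_number(start_s, "start_s")
  check_number(duration_s, "duration_s", min = 0)
  check_number(magnitude, "magnitude")
  fs <- wave_fs(w); t0 <- wave_t0(w)
  n <- nrow(w)
  if (start_s < t0 - 1e-9 || start_s + duration_s > t0 + n / fs + 1e-9) {
    stop_respyre("Artifact interval lies outside the signal extent.",
                 "respyre_signal_error")
  }
  i0 <- max(1L, floor((start_s - t0) * fs) + 1L)
  i1 <- min(n, ceiling((start_s + duration_s - t0) * fs))
  if (i1 < i0) return(w)
  idx <- i0:i1
  x <- w$amplitude
  if (kind == "spike") {
    u <- (seq_along(idx) - 0.5) / length(idx)
    x[idx] <- x[idx] + magnitude * sin(pi * u)
  } else if (kind == "step") {
    x[idx] <- x[idx] + magnitude
  } else {
    x[idx] <- x[i0]
  }
  wave_update(w, x)
}

#' Reference respiratory rate per analysis window
#'
#' Counts ground-truth breath onsets per half-open window and converts to
#' breaths/min. For a constant-rate recording this reproduces the configured
#' rate exactly on integer-minute windows.
#'
#' @param breaths Tibble with column `onset_s` (e.g. from [generate_ppg()]).
#' @param duration_s Total signal duration, seconds.
#' @param window_s Window length, seconds (default 60).
#' @return Tibble with `window`, `start_s`, `end_s`, `rr_ref`.
#' @export
window_reference_rr <- function(breaths, duration_s, window_s = 60) {
  starts <- seq(0, duration_s - window_s, by = window_s)
  tibble(
    window = seq_along(starts),
    start_s = starts,
    end_s = starts + window_s,
    rr_ref = vapply(starts, function(s) {
      60 * sum(breaths$onset_s >= s & breaths$onset_s < s + window_s) / window_s
    }, numeric(1))
  )
}

#' Generate a cohort of synthetic subjects
#'
#' Convenience wrapper producing one synthetic PPG record per subject, with
#' per-subject heart and respiratory rates. Used by the end-to-end pipelines
#' and tests as the stand-in for a clinical dataset.
#'
#' @param n_subjects Number of subjects.
#' @param duration_s Record length per subject, seconds (default 480, i.e.
#'   8 min as in the public benchmarks).
#' @param resp_rate Scalar, vector (recycled across subjects), or `NULL` to
#'   draw uniformly from `rr_range`.
#' @param heart_rate Scalar, vector, or `NULL` to draw uniformly from
#'   `hr_range`.
#' @param rr_range,hr_range Sampling ranges used when rates are not given.
#' @param sampling_rate,bw_depth,am_depth,fm_depth,noise_sd,notch_amplitude
#'   Passed to [synth_config()].
#' @param seed Integer seed controlling both rate draws and per-record noise.
#' @return Tibble with one row per subject: `subject`, `heart_rate`,
#'   `resp_rate`, and list-columns `ppg` (waveforms) and `breaths`.
#' @export
synth_cohort <- function(n_subjects, duration_s = 480, resp_rate = NULL,
                         heart_rate = NULL, rr_range = c(8, 30),
                         hr_range = c(60, 90), sampling_rate = 125,
                         bw_depth = 0.1, am_depth = 0.1, fm_depth = 0.1,
                         noise_sd = 0.05, notch_amplitude = 0.2, seed = 1L) {
  check_number(n_subjects, "n_subjects", min = 1)
  rates <- with_seed_(derive_seed(seed, 1L), {
    list(
      rr = if (is.null(resp_rate)) runif(n_subjects, rr_range[1], rr_range[2])
           else rep_len(resp_rate, n_subjects),
      hr = if (is.null(heart_rate)) runif(n_subjects, hr_range[1], hr_range[2])
           else rep_len(heart_rate, n_subjects)
    )
  })
  recs <- purrr::map(seq_len(n_subjects), function(i) {
    generate_ppg(synth_config(
      duration_s = duration_s, sampling_rate = sampling_rate,
      heart_rate = rates$hr[i], resp_rate = rates$rr[i],
      bw_depth = bw_depth, am_depth = am_depth, fm_depth = fm_depth,
      noise_sd = noise_sd, notch_amplitude = notch_amplitude,
      seed = derive_seed(seed, 100L + i)
    ))
  })
  tibble(
    subject = sprintf("synth%02d", seq_len(n_subjects)),
    heart_rate = rates$hr,
    resp_rate = rates$rr,
    ppg = purrr::map(recs, "signal"),
    breaths = purrr::map(recs, "breaths")
  )
}
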