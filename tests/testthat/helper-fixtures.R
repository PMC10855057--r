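# shared fixtures: small deterministic signals built in code

sine_wave <- function(freq_hz, fs, duration_s, amplitude = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  wave_signal(amplitude * sin(2 * pi * freq_hz * t + phase), fs = fs)
}

# steady-state amplitude gain of a filter measured on a sinusoid, ignoring
# the first/last 10% of samples
measured_gain <- function(w_in, w_out, trim = 0.1) {
  n <- nrow(w_in)
  i <- seq(ceiling(n * trim), floor(n * (1 - trim)))
  sqrt(sum(w_out$amplitude[i]^2) / sum(w_in$amplitude[i]^2))
}

# dominant periodogram frequency of a numeric vector
dominant_freq <- function(x, fs) {
  sp <- welch_psd(x - mean(x), fs, seg_s = length(x) / fs)
  sp$frequency[which.max(sp$power)]
}

# deterministic sinusoid windows + pooled labels for network tests
make_label_dataset <- function(n, config, rr_range = c(8, 30), noise_sd = 0,
                               seed = 1) {
  withr::with_seed(seed, {
    t <- (seq_len(config$window_samples) - 1) / config$input_rate
    X <- t(sapply(seq_len(n), function(i) {
      x <- 2 * sin(2 * pi * runif(1, rr_range[1], rr_range[2]) / 60 * t +
                     runif(1, 0, 2 * pi))
      if (noise_sd > 0) x <- x + rnorm(length(t), sd = noise_sd)
      x
    }))
    Y <- t(apply((X > 0) * 1L, 1, function(y) respyre:::pool_labels(y, config)))
    list(x = X, y = Y)
  })
}
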