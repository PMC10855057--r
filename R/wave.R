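#' Uniformly sampled waveform signals
#'
#' A `resp_wave` is a tibble with columns `time` (seconds) and `amplitude`
#' (arbitrary units) plus attributes `fs` (sampling rate, Hz) and `t0` (time of
#' the first sample). It is the carrier for raw PPG, filtered PPG, and
#' respiratory surrogate signals.
#'
#' @param amplitude Numeric vector of sample values (all finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, seconds.
#' @param provenance Optional string recording how the signal was derived
#'   (e.g. `"am"`, `"filter_based"`).
#' @return A tibble of class `resp_wave`.
#' @export
#' @examples
#' w <- wave_signal(sin(2 * pi * 0.25 * seq(0, 10, by = 0.1)), fs = 10)
#' wave_fs(w)
wave_signal <- function(amplitude, fs, t0 = 0, provenance = NULL) {
  check_number(fs, "fs", min = .Machine$double.eps)
  check_number(t0, "t0")
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) && !all(is.finite(amplitude))) {
    stop_respyre("`amplitude` must contain only finite values.", "respyre_signal_error")
  }
  out <- tibble(
    time = t0 + (seq_along(amplitude) - 1) / fs,
    amplitude = amplitude
  )
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "t0") <- as.numeric(t0)
  attr(out, "provenance") <- provenance
  class(out) <- c("resp_wave", class(out))
  out
}

#' Coerce a data frame to a waveform signal
#'
#' Accepts a `resp_wave`, a two-column data frame (`time`, `amplitude`), or a
#' bare numeric vector. The sampling rate is taken from `fs`, the `"fs"`
#' attribute, or inferred from the median spacing of `time`.
#'
#' @param x Object to coerce.
#' @param fs Sampling rate in Hz; required when it cannot be inferred.
#' @return A `resp_wave` tibble.
#' @export
as_wave <- function(x, fs = NULL) {
  if (inherits(x, "resp_wave") && is.null(fs)) return(x)
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(fs)) stop_respyre("`fs` is required for a bare vector.", "respyre_signal_error")
    return(wave_signal(x, fs = fs))
  }
  if (is.data.frame(x)) {
    if (!all(c("time", "amplitude") %in% names(x))) {
      stop_respyre("Data frame must have `time` and `amplitude` columns.", "respyre_format_error")
    }
    fs <- fs %||% attr(x, "fs")
    if (is.null(fs)) {
      dt <- stats::median(diff(x$time))
      if (!is.finite(dt) || dt <= 0) {
        stop_respyre("Cannot infer the sampling rate from `time`.", "respyre_signal_error")
      }
      fs <- 1 / dt
    }
    return(wave_signal(x$amplitude, fs = fs, t0 = x$time[1] %||% 0,
                       provenance = attr(x, "provenance")))
  }
  stop_respyre("Cannot coerce this object to a waveform signal.", "respyre_signal_error")
}

#' @rdname wave_signal
#' @param x A `resp_wave` (or coercible data frame).
#' @export
wave_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) fs <- attr(as_wave(x), "fs")
  fs
}

#' @rdname wave_signal
#' @export
wave_t0 <- function(x) {
  t0 <- attr(x, "t0")
  if (is.null(t0)) t0 <- x$time[1] %||% 0
  t0
}

#' @rdname wave_signal
#' @export
wave_duration <- function(x) {
  nrow(x) / wave_fs(x)
}

# replace the samples of a wave, keeping rate and origin
wave_update <- function(x, amplitude, fs = wave_fs(x), t0 = wave_t0(x),
                        provenance = attr(x, "provenance")) {
  wave_signal(amplitude, fs = fs, t0 = t0, provenance = provenance)
}

#' @export
print.resp_wave <- function(x, ...) {
  cat(sprintf("<resp_wave> %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x), wave_fs(x), wave_duration(x),
              if (!is.null(attr(x, "provenance"))) paste0(" [", attr(x, "provenance"), "]") else ""))
  NextMethod()
}

#' Plot a waveform signal
#'
#' @param object A `resp_wave`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resp_wave <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$amplitude)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "amplitude",
         title = attr(object, "provenance") %||% "waveform") +
    theme_minimal()
}
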