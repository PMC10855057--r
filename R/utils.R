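# internal helpers: argument checking and seeded evaluation

stop_respyre <- function(msg, class) {
  rlang::abort(msg, class = c(class, "respyre_error"))
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_respyre(sprintf("`%s` must be supplied.", name), "respyre_config_error")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_respyre(
      sprintf("`%s` must be a single finite number in [%s, %s], got %s.",
              name, format(min), format(max), paste(format(x), collapse = ", ")),
      "respyre_config_error"
    )
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_respyre(sprintf("`%s` must be TRUE or FALSE.", name), "respyre_config_error")
  }
  invisible(x)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a stream-specific 32-bit seed from a base seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 7919L
}
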