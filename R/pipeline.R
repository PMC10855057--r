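#' Pipeline configuration
#'
#' A single validated configuration document driving the end-to-end
#' pipelines. Unknown keys are rejected before any computation. The global
#' `seed` propagates to every stochastic stage (synthetic generation, data
#' splits, network initialisation and batching).
#'
#' @param source Input description: `list(kind = "synthetic", n_subjects =,
#'   duration_s =, resp_rate =, heart_rate =, bw_depth =, am_depth =,
#'   fm_depth =, noise_sd =, notch_amplitude =)` or `list(kind = "bidmc",
#'   dir =)` / `list(kind = "capnobase", dir =)` pointing at a directory of
#'   records.
#' @param extract Extraction settings: `method` (`"feature"` or
#'   `"filter_based"`), `kinds` (feature kinds, default BW/AM/FM),
#'   `resample` (`"linear"`, `"cubic_spline"`, `"berger"`), `rate_hz`.
#' @param estimator `"spectral"`, `"zero_crossing"`, or `"trough_peak"`.
#' @param fusion `"smart"`, `"spectral_avg"`, or `"none"`.
#' @param temporal_k Temporal median length (0 disables smoothing).
#' @param window_s Analysis window, seconds.
#' @param model A [model_config()] (deep pipeline only).
#' @param evaluation `list(flag_fluctuations = FALSE, sd_factor = 3,
#'   rail_frac = 0.1)`.
#' @param output_dir Optional directory: per-window estimates, the report
#'   and a run manifest are written there.
#' @param log_level `"info"` or `"quiet"`.
#' @param seed Global integer seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = list(kind = "synthetic"),
                            extract = list(), estimator = "spectral",
                            fusion = "smart", temporal_k = 3, window_s = 60,
                            model = model_config(), evaluation = list(),
                            output_dir = NULL, log_level = "info",
                            seed = 1L) {
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop_respyre(sprintf("Unknown %s key(s): %s", what,
                           paste(bad, collapse = ", ")),
                   "respyre_config_error")
    }
  }
  check_keys(source, c("kind", "n_subjects", "duration_s", "resp_rate",
                       "heart_rate", "bw_depth", "am_depth", "fm_depth",
                       "noise_sd", "notch_amplitude", "dir"), "source")
  check_keys(extract, c("method", "kinds", "resample", "rate_hz"), "extract")
  check_keys(evaluation, c("flag_fluctuations", "sd_factor", "rail_frac"),
             "evaluation")
  source <- modifyList(list(kind = "synthetic", n_subjects = 5,
                            duration_s = 480, resp_rate = NULL,
                            heart_rate = NULL, bw_depth = 0.1, am_depth = 0.1,
                            fm_depth = 0.1, noise_sd = 0.05,
                            notch_amplitude = 0.2, dir = NULL),
                       source, keep.null = TRUE)
  extract <- modifyList(list(method = "feature", kinds = c("bw", "am", "fm"),
                             resample = "linear", rate_hz = 4), extract)
  evaluation <- modifyList(list(flag_fluctuations = FALSE, sd_factor = 3,
                                rail_frac = 0.1), evaluation)
  if (!source$kind %in% c("synthetic", "bidmc", "capnobase")) {
    stop_respyre("source$kind must be synthetic, bidmc or capnobase.",
                 "respyre_config_error")
  }
  if (!estimator %in% c("spectral", "zero_crossing", "trough_peak")) {
    stop_respyre(sprintf("Unknown estimator '%s'.", estimator), "respyre_config_error")
  }
  if (!fusion %in% c("smart", "spectral_avg", "none")) {
    stop_respyre(sprintf("Unknown fusion '%s'.", fusion), "respyre_config_error")
  }
  if (!extract$method %in% c("feature", "filter_based")) {
    stop_respyre("extract$method must be 'feature' or 'filter_based'.",
                 "respyre_config_error")
  }
  check_number(temporal_k, "temporal_k", min = 0)
  check_number(window_s, "window_s", min = 1)
  check_number(seed, "seed")
  if (is.list(model) && !inherits(model, "model_config")) {
    model <- do.call(model_config, model)
  }
  structure(
    list(source = source, extract = extract, estimator = estimator,
         fusion = fusion, temporal_k = temporal_k, window_s = window_s,
         model = model, evaluation = evaluation, output_dir = output_dir,
         log_level = log_level, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML (or JSON) configuration document mirroring the
#'   argument structure.
#' @export
pipeline_config_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(pipeline_config, doc)
}

log_stage <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf("[respyre] %s", sprintf(fmt, ...)))
  }
}

# load records as a cohort tibble: subject, resp_rate (NA if unknown),
# ppg (list of waves), breaths (list or NULL), rr_series (list or NULL)
load_cohort <- function(config) {
  src <- config$source
  if (src$kind == "synthetic") {
    co <- synth_cohort(
      n_subjects = src$n_subjects, duration_s = src$duration_s,
      resp_rate = src$resp_rate, heart_rate = src$heart_rate,
      bw_depth = src$bw_depth, am_depth = src$am_depth,
      fm_depth = src$fm_depth, noise_sd = src$noise_sd,
      notch_amplitude = src$notch_amplitude, seed = config$seed
    )
    co$rr_series <- vector("list", nrow(co))
    return(co)
  }
  if (is.null(src$dir) || !dir.exists(src$dir)) {
    stop_respyre("source$dir must point at a directory of records.",
                 "respyre_config_error")
  }
  if (src$kind == "bidmc") {
    prefixes <- unique(sub("_Signals\\.csv$", "",
                           list.files(src$dir, pattern = "_Signals\\.csv$",
                                      full.names = TRUE)))
    recs <- purrr::map(prefixes, read_bidmc_record)
  } else {
    prefixes <- unique(sub("_data\\.csv$", "",
                           list.files(src$dir, pattern = "_data\\.csv$",
                                      full.names = TRUE)))
    recs <- purrr::map(prefixes, read_capnobase_record)
  }
  if (!length(recs)) {
    stop_respyre("No records found in source$dir.", "respyre_format_error")
  }
  tibble(
    subject = purrr::map_chr(recs, "subject_id"),
    heart_rate = NA_real_,
    resp_rate = NA_real_,
    ppg = purrr::map(recs, "ppg"),
    breaths = purrr::map(recs, "reference_breaths"),
    rr_series = purrr::map(recs, "reference_rr_series")
  )
}

# reference RR per analysis window for one cohort row
reference_rr_windows <- function(row, window_s) {
  duration <- wave_duration(row$ppg[[1]])
  if (!is.null(row$breaths[[1]])) {
    return(window_reference_rr(row$breaths[[1]], duration, window_s))
  }
  if (!is.null(row$rr_series[[1]])) {
    rs <- row$rr_series[[1]]
    starts <- seq(0, duration - window_s, by = window_s)
    return(tibble(
      window = seq_along(starts), start_s = starts, end_s = starts + window_s,
      rr_ref = vapply(starts, function(s) {
        mean(rs$rr[rs$time_s >= s & rs$time_s < s + window_s], na.rm = TRUE)
      }, numeric(1))
    ))
  }
  stop_respyre("Record carries no breathing reference.", "respyre_data_error")
}

estimator_fun <- function(name) {
  switch(name,
         spectral = rr_spectral,
         zero_crossing = rr_zero_crossing,
         trough_peak = rr_trough_peak)
}

# classical chain for one subject: returns per-window estimates
classical_subject <- function(row, config) {
  ppg <- row$ppg[[1]]
  est_fun <- estimator_fun(config$estimator)
  hp <- highpass_vlf(ppg)
  rate <- config$extract$rate_hz
  if (config$extract$method == "feature") {
    lp <- lowpass_ppg(hp)
    beats <- segment_pulses(lp)
    resp <- purrr::map(config$extract$kinds, function(k) {
      resample_features(beat_features(beats, k),
                        method = config$extract$resample, target_rate = rate)
    })
    names(resp) <- config$extract$kinds
  } else {
    resp <- list(filter_based = extract_filter_based(hp, target_rate = rate))
  }

  refw <- reference_rr_windows(row, config$window_s)
  ests <- purrr::pmap(refw, function(window, start_s, end_s, rr_ref) {
    # clip the window to the common extent of the surrogate signals
    ext_lo <- max(purrr::map_dbl(resp, wave_t0))
    ext_hi <- min(purrr::map_dbl(resp, ~ wave_t0(.x) + wave_duration(.x)))
    lo <- max(start_s, ext_lo); hi <- min(end_s, ext_hi)
    if (hi - lo < 0.75 * (end_s - start_s)) {
      return(tibble(method = config$fusion, start_s = start_s, end_s = end_s,
                    rr = NA_real_, valid = FALSE))
    }
    per_mod <- purrr::map(resp, ~ est_fun(.x, window = c(lo, hi)))
    fused <- if (config$fusion == "smart" && length(per_mod) == 3) {
      smart_fusion(dplyr::bind_rows(per_mod))
    } else if (config$fusion == "spectral_avg") {
      sp <- purrr::map(resp, function(w) {
        s <- wave_window(w, c(lo, hi))
        welch_psd(s$x, s$fs)
      })
      spectral_peak_average(sp)
    } else {
      per_mod[[1]]
    }
    tibble(method = fused$method, start_s = start_s, end_s = end_s,
           rr = fused$rr, valid = fused$valid)
  })
  ests <- dplyr::bind_rows(ests)
  if (config$temporal_k > 0) {
    ests <- temporal_smooth(ests, k = config$temporal_k)
  } else {
    ests <- dplyr::mutate(ests, rr_smooth = .data$rr, valid_smooth = .data$valid)
  }
  dplyr::mutate(refw, subject = row$subject,
                rr_est = ests$rr_smooth, rr_raw = ests$rr,
                valid = ests$valid_smooth)
}

write_outputs <- function(config, report, extra = list()) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(report, file.path(config$output_dir, "report.json"))
  readr::write_csv(report$windows, file.path(config$output_dir, "estimates.csv"))
  manifest <- list(
    package = "respyre",
    version = as.character(utils::packageVersion("respyre")),
    seed = config$seed,
    config = unclass_config(config)
  )
  jsonlite::write_json(c(manifest, extra),
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$model <- unclass(out$model)
  out
}

#' Run the classical RR-estimation pipeline end to end
#'
#' Preprocess (very-low-frequency removal, PPG low-pass), extract respiratory
#' surrogates (beat features or filter-based), estimate RR per window, fuse
#' (smart fusion or spectral peak-conditioned averaging), smooth temporally,
#' and evaluate against the breathing reference.
#'
#' @param config A [pipeline_config()].
#' @return An [evaluation_report()] (`rr_report`) whose `windows` carry
#'   per-subject, per-window reference and estimate.
#' @export
run_classical_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_respyre("`config` must be a pipeline_config().", "respyre_config_error")
  }
  cohort <- load_cohort(config)
  log_stage(config, "classical pipeline: %d subject(s)", nrow(cohort))
  windows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    classical_subject(cohort[i, ], config)
  })
  windows <- dplyr::bind_rows(windows)
  report <- evaluation_report(windows)
  write_outputs(config, report)
  report
}

# deep-pipeline data preparation: 30 Hz z-scored respiratory signal cut into
# minutes and model windows
deep_prepare <- function(cohort, config) {
  mc <- config$model
  win <- mc$window_samples
  purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    hp <- highpass_vlf(row$ppg[[1]])
    if (config$extract$method == "feature") {
      beats <- segment_pulses(lowpass_ppg(hp))
      resp <- resample_features(beat_features(beats, config$extract$kinds[1]),
                                method = config$extract$resample,
                                target_rate = mc$input_rate)
    } else {
      resp <- extract_filter_based(hp, target_rate = mc$input_rate)
    }
    # regrid onto the record's full extent (constant-edge extension) so each
    # record contributes its full complement of minutes
    full_t <- seq(0, wave_duration(row$ppg[[1]]) - 1 / mc$input_rate,
                  by = 1 / mc$input_rate)
    resp <- wave_signal(stats::approx(resp$time, resp$amplitude, xout = full_t,
                                      rule = 2)$y,
                        fs = mc$input_rate, provenance = attr(resp, "provenance"))
    resp <- zscore_clip(resp)
    x <- resp$amplitude
    n_min <- floor(length(x) / (60 * mc$input_rate))
    per_min <- 60 * mc$input_rate
    wins_per_min <- per_min %/% win
    # per-minute breathing reference: generator truth, else the RR series
    rr_min <- rep(row$resp_rate, n_min)
    if (all(is.na(rr_min)) && !is.null(row$rr_series[[1]])) {
      rs <- row$rr_series[[1]]
      rr_min <- vapply(seq_len(n_min), function(m) {
        mean(rs$rr[rs$time_s >= (m - 1) * 60 & rs$time_s < m * 60], na.rm = TRUE)
      }, numeric(1))
    }
    out <- list()
    for (m in seq_len(n_min)) {
      base <- (m - 1) * per_min
      for (k in seq_len(wins_per_min)) {
        seg <- x[base + (k - 1) * win + seq_len(win)]
        out[[length(out) + 1]] <- tibble(
          subject = row$subject, minute = m, win = k,
          rr_ref = rr_min[m],
          samples = list(seg), labels = list(label_breath_phase(seg))
        )
      }
    }
    dplyr::bind_rows(out)
  }) |> dplyr::bind_rows()
}

#' Run the deep RR-estimation pipeline end to end
#'
#' Preprocess (respiratory band-pass, resample to 30 Hz, z-score and clip),
#' self-label inhalation/exhalation at the zero line, split train /
#' validation / test (subject-disjoint), train the CNN-LSTM classifier, and
#' evaluate: for each test minute the predictions of its consecutive windows
#' are concatenated and RR is the inhalation-onset count over the covered
#' duration.
#'
#' @param config A [pipeline_config()]; `config$model` holds the network
#'   settings.
#' @param epochs Optional override of `config$model$epochs`.
#' @return A list of class `deep_rr_result`: `report` (an `rr_report` over
#'   test minutes), `fit` (the [train_model()] result), and `windows` (the
#'   split dataset).
#' @export
run_deep_pipeline <- function(config, epochs = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop_respyre("`config` must be a pipeline_config().", "respyre_config_error")
  }
  mc <- config$model
  cohort <- load_cohort(config)
  log_stage(config, "deep pipeline: preparing %d subject(s)", nrow(cohort))
  windows <- deep_prepare(cohort, config)
  windows <- split_dataset(windows, split_ratio = mc$split_ratio,
                           val_fraction = mc$val_fraction,
                           seed = config$seed, by_subject = TRUE)
  model <- build_model(mc)
  log_stage(config, "training on %d windows (%d validation)",
            sum(windows$split == "train"), sum(windows$split == "validation"))
  fit <- train_model(model,
                     train = dplyr::filter(windows, .data$split == "train"),
                     validation = dplyr::filter(windows, .data$split == "validation"),
                     epochs = epochs)
  test <- dplyr::filter(windows, .data$split == "test")
  log_stage(config, "evaluating %d test windows", nrow(test))
  per_minute <- test |>
    dplyr::group_by(.data$subject, .data$minute) |>
    dplyr::arrange(.data$win, .by_group = TRUE) |>
    dplyr::summarise(
      rr_ref = .data$rr_ref[1],
      rr_est = {
        X <- do.call(rbind, .data$samples)
        lab <- predict_labels(fit, X)
        dur <- nrow(X) * mc$window_samples / mc$input_rate
        rr_from_labels(as.integer(t(lab)), dur)$rr
      },
      .groups = "drop"
    )
  report <- evaluation_report(
    dplyr::mutate(per_minute, window = .data$minute,
                  start_s = (.data$minute - 1) * 60,
                  end_s = .data$minute * 60)
  )
  write_outputs(config, report,
                extra = list(best_epoch = fit$best_epoch,
                             best_val_loss = fit$best_val_loss))
  structure(list(report = report, fit = fit, windows = windows),
            class = "deep_rr_result")
}

#' @export
print.deep_rr_result <- function(x, ...) {
  print(x$fit)
  print(x$report)
  invisible(x)
}

#' @rdname run_deep_pipeline
#' @param x,object A `deep_rr_result`.
#' @param ... Unused.
#' @export
glance.deep_rr_result <- function(x, ...) {
  dplyr::bind_cols(glance(x$report), glance(x$fit))
}

#' @rdname run_deep_pipeline
#' @export
tidy.deep_rr_result <- function(x, ...) tidy(x$report)
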