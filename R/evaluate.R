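#' @name rr_metrics
#' @title Agreement metrics for respiratory-rate estimates
#'
#' @description
#' Window-wise agreement between reference and estimated RR: mean absolute
#' error (MAE), root-mean-square error (RMSE), signed percentage error per
#' pair (aggregated as mean absolute percentage error), and CP2 — the
#' percentage of windows whose absolute error is within 2 breaths/min
#' (inclusive). Pairs whose estimate is missing (`NA`, i.e. the fusion
#' abstained) are excluded from the mean and counted separately.
#'
#' @param ref,est Numeric vectors of equal length: reference and estimated
#'   RR in breaths/min.
#' @return A single number (breaths/min for MAE/RMSE, percent for
#'   `rr_mape()` and `cp2()`); `percentage_error()` returns a signed vector.
NULL

paired_complete <- function(ref, est) {
  if (length(ref) != length(est) || !length(ref)) {
    stop_respyre("`ref` and `est` must be non-empty vectors of equal length.",
                 "respyre_data_error")
  }
  keep <- is.finite(ref) & is.finite(est)
  if (!any(keep)) {
    stop_respyre("No valid reference/estimate pairs remain.", "respyre_data_error")
  }
  list(ref = ref[keep], est = est[keep], n_excluded = sum(!keep))
}

#' @rdname rr_metrics
#' @export
rr_mae <- function(ref, est) {
  p <- paired_complete(ref, est)
  mean(abs(p$ref - p$est))
}

#' @rdname rr_metrics
#' @export
rr_rmse <- function(ref, est) {
  p <- paired_complete(ref, est)
  sqrt(mean((p$ref - p$est)^2))
}

#' @rdname rr_metrics
#' @export
percentage_error <- function(ref, est) {
  if (any(ref == 0, na.rm = TRUE)) {
    stop_respyre("Percentage error is undefined for a zero reference.",
                 "respyre_data_error")
  }
  (est - ref) / ref * 100
}

#' @rdname rr_metrics
#' @export
rr_mape <- function(ref, est) {
  p <- paired_complete(ref, est)
  mean(abs(percentage_error(p$ref, p$est)))
}

#' @rdname rr_metrics
#' @param threshold_bpm CP threshold in breaths/min (default 2).
#' @export
cp2 <- function(ref, est, threshold_bpm = 2) {
  p <- paired_complete(ref, est)
  100 * mean(abs(p$ref - p$est) <= threshold_bpm)
}

#' Build an evaluation report from per-window estimates
#'
#' @param windows A tibble with columns `rr_ref` and `rr_est` (plus any
#'   identifying columns such as `subject`, `window`, `start_s`, `end_s`).
#'   Rows with `NA` estimates (abstentions) are excluded from the metrics
#'   and counted.
#' @param excluded Optional tibble of windows excluded before evaluation
#'   (e.g. from [flag_fluctuation_segments()]), with a `reason` column.
#' @return An object of class `rr_report`; see [glance.rr_report()] for the
#'   one-row metric summary and [tidy.rr_report()] for per-window rows.
#' @export
evaluation_report <- function(windows, excluded = NULL) {
  if (!all(c("rr_ref", "rr_est") %in% names(windows))) {
    stop_respyre("`windows` needs `rr_ref` and `rr_est` columns.",
                 "respyre_data_error")
  }
  excluded <- excluded %||% tibble(reason = character())
  p <- paired_complete(windows$rr_ref, windows$rr_est)
  metrics <- tibble(
    mae = mean(abs(p$ref - p$est)),
    rmse = sqrt(mean((p$ref - p$est)^2)),
    mape = mean(abs(percentage_error(p$ref, p$est))),
    cp2 = 100 * mean(abs(p$ref - p$est) <= 2),
    n_windows = nrow(windows),
    n_abstained = p$n_excluded,
    n_excluded = nrow(excluded)
  )
  structure(list(metrics = metrics, windows = as_tibble(windows),
                 excluded = as_tibble(excluded)),
            class = "rr_report")
}

#' @export
print.rr_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<rr_report> %d windows (%d abstained, %d excluded)\n  MAE %.2f | RMSE %.2f | %.1f%% abs. error | CP2 %.1f%%\n",
    m$n_windows, m$n_abstained, m$n_excluded, m$mae, m$rmse, m$mape, m$cp2))
  invisible(x)
}

#' Tidiers for evaluation reports
#'
#' `tidy()` returns per-window rows with the signed error; `glance()` the
#' one-row metric summary.
#'
#' @param x An `rr_report`.
#' @param ... Unused.
#' @export
tidy.rr_report <- function(x, ...) {
  dplyr::mutate(x$windows,
                error = .data$rr_est - .data$rr_ref,
                abs_error = abs(.data$error))
}

#' @rdname tidy.rr_report
#' @export
glance.rr_report <- function(x, ...) x$metrics

#' @rdname tidy.rr_report
#' @param object An `rr_report`.
#' @export
autoplot.rr_report <- function(object, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  ggplot(d, aes(x = .data$rr_ref, y = .data$rr_est)) +
    geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "reference RR (breaths/min)", y = "estimated RR (breaths/min)") +
    theme_minimal()
}

#' Flag fluctuation-corrupted signal windows
#'
#' Automates the visual exclusion of artifact-ridden one-minute segments: a
#' window is flagged when its sample standard deviation exceeds `sd_factor`
#' times the subject's median window SD, or when more than `rail_frac` of
#' its samples sit at the clip rails (±`rail`). Flagged windows are reported
#' with reasons, never silently dropped.
#'
#' @param windows A tibble with a `samples` list-column (e.g. from
#'   [segment_windows()]); a `subject` column groups the median.
#' @param sd_factor SD ratio threshold (default 3).
#' @param rail_frac Maximum tolerated fraction of rail-sitting samples
#'   (default 0.1).
#' @param rail Clip rail magnitude (default 2, matching [zscore_clip()]).
#' @return A tibble of flagged windows (identifying columns plus `reason`);
#'   zero rows when nothing is flagged.
#' @export
flag_fluctuation_segments <- function(windows, sd_factor = 3, rail_frac = 0.1,
                                      rail = 2) {
  if (!"samples" %in% names(windows)) {
    stop_respyre("`windows` needs a `samples` list-column.", "respyre_data_error")
  }
  grp <- if ("subject" %in% names(windows)) windows$subject else rep("all", nrow(windows))
  sds <- purrr::map_dbl(windows$samples, stats::sd)
  med <- stats::ave(sds, grp, FUN = stats::median)
  at_rail <- purrr::map_dbl(windows$samples,
                            ~ mean(abs(.x) >= rail - 1e-9))
  reason <- dplyr::case_when(
    med > 0 & sds > sd_factor * med & at_rail > rail_frac ~ "sd_ratio;clip_rail",
    med > 0 & sds > sd_factor * med ~ "sd_ratio",
    at_rail > rail_frac ~ "clip_rail",
    TRUE ~ NA_character_
  )
  out <- windows[!is.na(reason), setdiff(names(windows), "samples"), drop = FALSE]
  out$reason <- reason[!is.na(reason)]
  as_tibble(out)
}
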