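#' Subject records
#'
#' A `subject_record` bundles one subject's PPG with whatever reference
#' material the source provides: a reference respiration waveform, annotated
#' breath times, and/or a numeric RR time series. All contained signals share
#' the record's time origin.
#'
#' @param subject_id Non-empty identifier string.
#' @param ppg The PPG `resp_wave`.
#' @param reference_resp Optional reference respiration `resp_wave`.
#' @param reference_breaths Optional tibble with `onset_s`.
#' @param reference_rr_series Optional tibble with `time_s`, `rr`.
#' @param metadata Named list (age, gender, ...).
#' @return A list of class `subject_record`.
#' @export
subject_record <- function(subject_id, ppg, reference_resp = NULL,
                           reference_breaths = NULL,
                           reference_rr_series = NULL, metadata = list()) {
  if (!is.character(subject_id) || !nzchar(subject_id)) {
    stop_respyre("`subject_id` must be a non-empty string.", "respyre_format_error")
  }
  structure(
    list(subject_id = subject_id, ppg = as_wave(ppg),
         reference_resp = if (!is.null(reference_resp)) as_wave(reference_resp),
         reference_breaths = reference_breaths,
         reference_rr_series = reference_rr_series,
         metadata = metadata),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s: PPG %.0f s @ %g Hz%s%s%s\n",
              x$subject_id, wave_duration(x$ppg), wave_fs(x$ppg),
              if (!is.null(x$reference_resp)) ", reference respiration" else "",
              if (!is.null(x$reference_breaths)) sprintf(", %d annotated breaths",
                                                         nrow(x$reference_breaths)) else "",
              if (!is.null(x$reference_rr_series)) ", RR series" else ""))
  invisible(x)
}

read_csv_quiet <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  names(df) <- trimws(names(df))
  df
}

find_col <- function(df, pattern, file, required = TRUE) {
  hit <- grep(pattern, names(df), ignore.case = TRUE)
  if (!length(hit)) {
    if (required) {
      stop_respyre(sprintf("File '%s' lacks a column matching '%s'.",
                           basename(file), pattern),
                   "respyre_format_error")
    }
    return(NULL)
  }
  df[[hit[1]]]
}

#' Read a BIDMC-layout record
#'
#' Reads the PhysioNet CSV distribution layout: `<prefix>_Signals.csv`
#' (waveforms at 125 Hz, columns `Time [s]`, `PLETH`, `RESP`, ...),
#' `<prefix>_Numerics.csv` (1 Hz numerics including `HR` and `RESP`), and
#' `<prefix>_Breaths.csv` (annotated breath sample numbers). Numerics and
#' breath annotations are optional; signals are never resampled — rates are
#' reported as found.
#'
#' @param prefix Path prefix of the record (the part before `_Signals.csv`).
#' @param fs Fallback sampling rate when the signals file has no time
#'   column (default 125).
#' @return A [subject_record()].
#' @export
read_bidmc_record <- function(prefix, fs = 125) {
  sig_file <- paste0(prefix, "_Signals.csv")
  if (!file.exists(sig_file)) {
    stop_respyre(sprintf("Signals file not found: %s", sig_file),
                 "respyre_format_error")
  }
  sig <- read_csv_quiet(sig_file)
  time <- find_col(sig, "^Time", sig_file, required = FALSE)
  pleth <- find_col(sig, "^PLETH$", sig_file)
  resp <- find_col(sig, "^RESP$", sig_file, required = FALSE)
  if (!is.null(time) && length(time) > 1) {
    dt <- stats::median(diff(time))
    if (is.finite(dt) && dt > 0) fs <- 1 / dt
  }
  lens <- c(length(pleth), if (!is.null(resp)) length(resp))
  if (length(unique(lens)) != 1) {
    stop_respyre("Signal columns have inconsistent lengths.", "respyre_format_error")
  }
  ppg <- wave_signal(pleth, fs = fs, provenance = "ppg")
  ref_resp <- if (!is.null(resp)) wave_signal(resp, fs = fs, provenance = "reference_resp")

  rr_series <- NULL
  num_file <- paste0(prefix, "_Numerics.csv")
  if (file.exists(num_file)) {
    num <- read_csv_quiet(num_file)
    nt <- find_col(num, "^Time", num_file, required = FALSE)
    nr <- find_col(num, "^RESP$", num_file, required = FALSE)
    if (!is.null(nr)) {
      rr_series <- tibble(time_s = nt %||% (seq_along(nr) - 1), rr = nr)
    }
  }

  breaths <- NULL
  br_file <- paste0(prefix, "_Breaths.csv")
  if (file.exists(br_file)) {
    br <- read_csv_quiet(br_file)
    samp <- find_col(br, "breaths? ann", br_file, required = FALSE) %||%
      (if (ncol(br)) br[[1]])
    samp <- samp[is.finite(samp)]
    if (length(samp)) breaths <- tibble(onset_s = (samp - 1) / fs)
  }

  subject_record(
    subject_id = basename(prefix), ppg = ppg, reference_resp = ref_resp,
    reference_breaths = breaths, reference_rr_series = rr_series
  )
}

#' Write a record in the BIDMC CSV layout
#'
#' Counterpart of [read_bidmc_record()]; used to persist synthetic records
#' and for round-trip testing.
#'
#' @param record A [subject_record()].
#' @param dir Output directory (created if needed).
#' @param id Record identifier used as the file prefix (default the
#'   record's `subject_id`).
#' @return The path prefix, invisibly.
#' @export
write_bidmc_record <- function(record, dir, id = record$subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, id)
  fs <- wave_fs(record$ppg)
  sig <- data.frame(`Time [s]` = record$ppg$time, PLETH = record$ppg$amplitude,
                    check.names = FALSE)
  if (!is.null(record$reference_resp)) sig$RESP <- record$reference_resp$amplitude
  readr::write_csv(sig, paste0(prefix, "_Signals.csv"))
  if (!is.null(record$reference_rr_series)) {
    num <- data.frame(`Time [s]` = record$reference_rr_series$time_s,
                      RESP = record$reference_rr_series$rr, check.names = FALSE)
    readr::write_csv(num, paste0(prefix, "_Numerics.csv"))
  }
  if (!is.null(record$reference_breaths)) {
    br <- data.frame(`breaths ann1 [signal sample no]` =
                       round(record$reference_breaths$onset_s * fs) + 1,
                     check.names = FALSE)
    readr::write_csv(br, paste0(prefix, "_Breaths.csv"))
  }
  invisible(prefix)
}

#' Read a CapnoBase-layout record (CSV export)
#'
#' Reads the per-record CSV export layout: `<prefix>_data.csv` with columns
#' `time_s`, `ppg`, and optionally `co2` (the capnogram), plus an optional
#' `<prefix>_breaths.csv` with expert breath times (`breath_s`). MATLAB
#' containers are not read; export the record to CSV first.
#'
#' @param prefix Path prefix of the record (the part before `_data.csv`).
#' @return A [subject_record()].
#' @export
read_capnobase_record <- function(prefix) {
  data_file <- paste0(prefix, "_data.csv")
  if (!file.exists(data_file)) {
    stop_respyre(sprintf("Data file not found: %s", data_file),
                 "respyre_format_error")
  }
  df <- read_csv_quiet(data_file)
  time <- find_col(df, "^time", data_file)
  ppg <- find_col(df, "^ppg$|^pleth$", data_file)
  co2 <- find_col(df, "^co2$", data_file, required = FALSE)
  dt <- stats::median(diff(time))
  if (!is.finite(dt) || dt <= 0) {
    stop_respyre("Cannot infer the sampling rate from the time column.",
                 "respyre_format_error")
  }
  fs <- 1 / dt
  breaths <- NULL
  br_file <- paste0(prefix, "_breaths.csv")
  if (file.exists(br_file)) {
    br <- read_csv_quiet(br_file)
    bt <- find_col(br, "breath", br_file, required = FALSE) %||%
      (if (ncol(br)) br[[1]])
    bt <- bt[is.finite(bt)]
    if (length(bt)) breaths <- tibble(onset_s = bt)
  }
  subject_record(
    subject_id = basename(prefix),
    ppg = wave_signal(ppg, fs = fs, provenance = "ppg"),
    reference_resp = if (!is.null(co2)) wave_signal(co2, fs = fs,
                                                    provenance = "capnogram"),
    reference_breaths = breaths
  )
}

#' @rdname read_capnobase_record
#' @param record A [subject_record()].
#' @param dir Output directory.
#' @param id File prefix (default the record's `subject_id`).
#' @export
write_capnobase_record <- function(record, dir, id = record$subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, id)
  df <- data.frame(time_s = record$ppg$time, ppg = record$ppg$amplitude)
  if (!is.null(record$reference_resp)) df$co2 <- record$reference_resp$amplitude
  readr::write_csv(df, paste0(prefix, "_data.csv"))
  if (!is.null(record$reference_breaths)) {
    readr::write_csv(data.frame(breath_s = record$reference_breaths$onset_s),
                     paste0(prefix, "_breaths.csv"))
  }
  invisible(prefix)
}

#' Write and read evaluation reports
#'
#' JSON (`.json`) serialises the full report — metric summary, per-window
#' rows, and the excluded-window list; CSV (`.csv`) writes the per-window
#' rows only (header always present, even with zero windows).
#'
#' @param report An [evaluation_report()].
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "rr_report")) {
    stop_respyre("`report` must be an rr_report.", "respyre_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(metrics = report$metrics, windows = report$windows,
           excluded = report$excluded),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else if (ext == "csv") {
    readr::write_csv(report$windows, path)
  } else {
    stop_respyre("Report path must end in .json or .csv.", "respyre_format_error")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(metrics = as_tibble(obj$metrics),
         windows = as_tibble(obj$windows),
         excluded = as_tibble(obj$excluded)),
    class = "rr_report"
  )
}

#' Write a waveform as a two-column CSV
#'
#' @param signal A `resp_wave` or coercible data frame.
#' @param path Output CSV path (`time_s`, `amplitude`).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  w <- as_wave(signal)
  readr::write_csv(data.frame(time_s = w$time, amplitude = w$amplitude), path)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param fs Optional sampling rate override; inferred from `time_s`
#'   otherwise.
#' @export
read_signal_csv <- function(path, fs = NULL) {
  df <- read_csv_quiet(path)
  time <- find_col(df, "^time", path)
  amp <- find_col(df, "amplitude|value|signal|ppg", path)
  as_wave(data.frame(time = time, amplitude = amp), fs = fs)
}

#' Print the expected on-disk layout of a supported dataset
#'
#' @param dataset `"bidmc"` or `"capnobase"`.
#' @return The layout description, invisibly (printed as a side effect).
#' @export
dataset_layout <- function(dataset = c("bidmc", "capnobase")) {
  dataset <- match.arg(dataset)
  txt <- switch(dataset,
    bidmc = paste(
      "BIDMC CSV layout (PhysioNet distribution), one record per prefix:",
      "  <prefix>_Signals.csv   Time [s], PLETH, RESP, ... at 125 Hz",
      "  <prefix>_Numerics.csv  Time [s], HR, PULSE, RESP, SpO2 at 1 Hz",
      "  <prefix>_Breaths.csv   breaths ann1 [signal sample no], ...",
      sep = "\n"),
    capnobase = paste(
      "CapnoBase CSV export layout, one record per prefix:",
      "  <prefix>_data.csv      time_s, ppg, co2",
      "  <prefix>_breaths.csv   breath_s (expert breath times, seconds)",
      sep = "\n"))
  cat(txt, "\n")
  invisible(txt)
}
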