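#' Read a multichannel recording
#'
#' Reads either an EDF file or a per-channel CSV bundle (a directory with a
#' `manifest.json` naming each channel's role, file and sampling rate; each
#' channel file has columns `time_s,value`). Physically impossible samples
#' (SpO2 outside 0--100, non-positive heart rate) and missing values are
#' masked invalid, never dropped or imputed. The respiratory channel, the
#' SpO2 channel and at least one of heart rate or ECG must be present.
#'
#' @param path EDF file or bundle directory.
#' @param format `"auto"` (by path type), `"edf"`, or `"csv"`.
#' @param channel_map optional label-to-role map for EDF, see [read_edf()].
#' @param require_channels mandatory roles checked after reading; set to
#'   `character()` to skip the check.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           channel_map = NULL,
                           require_channels = c("resp", "spo2")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "csv" else "edf"
  }
  rec <- if (format == "edf") {
    read_edf(path, channel_map = channel_map)
  } else {
    read_csv_bundle(path)
  }
  have <- names(rec$channels)
  missing <- setdiff(require_channels, have)
  if (length(require_channels) > 0 &&
      !any(c("hr", "ecg") %in% have)) {
    missing <- c(missing, "hr (or ecg)")
  }
  if (length(missing) > 0) {
    stop("recording is missing mandatory channel role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rec
}

read_csv_bundle <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("CSV bundle manifest not found: ", mf_path, call. = FALSE)
  }
  mf <- jsonlite::fromJSON(mf_path, simplifyDataFrame = FALSE)
  channels <- list()
  for (ch in mf$channels) {
    f <- file.path(path, ch$file)
    if (!file.exists(f)) {
      stop("channel file missing for role '", ch$role, "': ", f,
           call. = FALSE)
    }
    df <- utils::read.csv(f)
    if (!all(c("time_s", "value") %in% names(df))) {
      stop("channel file ", f, " must have columns time_s,value",
           call. = FALSE)
    }
    if (nrow(df) >= 2) {
      dt <- stats::median(diff(df$time_s))
      if (abs(dt - 1 / ch$rate) > 1e-6 * max(1, 1 / ch$rate)) {
        stop("sample-rate mismatch for channel '", ch$role,
             "': manifest says ", ch$rate, " Hz but file spacing is ",
             format(1 / dt, digits = 6),
             " Hz (resampling is not performed)", call. = FALSE)
      }
    }
    channels[[ch$role]] <- list(values = df$value, rate = ch$rate,
                                valid = !is.na(df$value))
  }
  recording(channels,
            start_time = mf$start_time %||% 0,
            subject_id = mf$subject_id %||% "subject")
}

#' Write a recording as a per-channel CSV bundle
#'
#' Creates `path/` with `manifest.json` plus one `<role>.csv`
#' (`time_s,value`) per channel; invalid samples are written as empty
#' (missing) values.
#'
#' @param rec a [recording()].
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_csv_bundle <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (role in names(rec$channels)) {
    ch <- rec$channels[[role]]
    f <- paste0(role, ".csv")
    v <- ch$values
    v[!ch$valid] <- NA
    df <- data.frame(
      time_s = rec$start_time + (seq_along(v) - 1) / ch$rate,
      value = v)
    utils::write.csv(df, file.path(path, f), row.names = FALSE, na = "")
    entries[[length(entries) + 1L]] <-
      list(role = role, file = f, rate = ch$rate)
  }
  jsonlite::write_json(
    list(subject_id = rec$subject_id, start_time = rec$start_time,
         channels = entries),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a recording (EDF or CSV bundle)
#'
#' @param rec a [recording()].
#' @param path destination (file for EDF, directory for CSV).
#' @param format `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "csv")) {
  format <- match.arg(format)
  if (format == "edf") write_edf(rec, path) else write_csv_bundle(rec, path)
}

#' Write an event list to CSV
#'
#' One row per event (`subject_id,type,threshold,onset,duration,condition`),
#' deterministically ordered by onset. An empty list yields a header-only
#' file.
#'
#' @param events an `event_list`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)[, c("subject_id", "type", "threshold",
                                  "onset", "duration", "condition")]
  df <- df[order(df$onset, df$type, df$threshold), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an event list from CSV
#'
#' @param path CSV written by [write_events()].
#' @return an `event_list`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       type = "character",
                                       condition = "character"))
  if (nrow(df) == 0L) return(event_list())
  as_event_list(df)
}

#' Read a cohort summary table
#'
#' Reads a per-subject, per-condition outcome table from CSV or (when the
#' `readxl` package is available) XLSX, optionally renaming external
#' headers via `col_map`, and validates it: all outcome columns present,
#' unique subject ids, non-negative counts/durations, integer counts.
#'
#' @param path CSV or XLSX file.
#' @param col_map optional named character vector mapping file headers to
#'   the package's column names, e.g.
#'   `c("LongPauses_NoStim" = "pause_long_count_off")`.
#' @return a validated `cohort_table`.
#' @export
read_cohort_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package; export to CSV instead",
           call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("cohort table is empty: ", path, call. = FALSE)
  }
  if (!is.null(col_map)) {
    unknown <- setdiff(names(col_map), names(df))
    if (length(unknown) > 0) {
      stop("col_map refers to header(s) not in the file: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    names(df)[match(names(col_map), names(df))] <- unname(col_map)
  }
  df$subject_id <- as.character(df$subject_id)
  validate_cohort(df)
}

#' Write a cohort summary table to CSV
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
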