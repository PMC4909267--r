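#' Multichannel cardiorespiratory recording
#'
#' A `recording` bundles synchronized physiological channels on a common time
#' origin: respiratory effort (`resp`, arbitrary units), pulse-oximetry oxygen
#' saturation (`spo2`, percent), heart rate (`hr`, beats/min) and optionally a
#' raw electrocardiogram (`ecg`, mV). Channels may be sampled at different
#' rates (NICU monitors typically emit vitals trends at ~1 Hz while effort and
#' ECG run at hundreds of Hz); each channel carries its own validity mask so
#' artifact is excluded from analysis rather than imputed.
#'
#' @param channels named list; each element is a list with components
#'   `values` (numeric vector), `rate` (sampling rate in Hz, > 0) and
#'   optionally `valid` (logical vector, same length as `values`; defaults to
#'   all `TRUE`). Recognised roles are `resp`, `spo2`, `hr`, `ecg`; other
#'   names are carried through untouched.
#' @param start_time recording start, seconds (time offset of the first
#'   sample of every channel).
#' @param subject_id opaque subject identifier.
#'
#' @details Physically impossible samples are masked on construction: SpO2
#'   outside \[0, 100\] and non-positive heart rates are marked invalid (the
#'   sample values are kept so no data are silently altered).
#'
#' @return An object of class `recording`.
#' @export
recording <- function(channels, start_time = 0, subject_id = "subject") {
  stopifnot(is.list(channels), length(channels) > 0, !is.null(names(channels)))
  roles <- names(channels)
  channels <- lapply(roles, function(role) {
    ch <- channels[[role]]
    if (is.numeric(ch)) ch <- list(values = ch)
    stopifnot(is.numeric(ch$values))
    if (is.null(ch$rate)) {
      stop("channel '", role, "': sampling rate missing", call. = FALSE)
    }
    if (!is.numeric(ch$rate) || length(ch$rate) != 1L || ch$rate <= 0) {
      stop("channel '", role, "': sample rate must be a positive scalar",
           call. = FALSE)
    }
    if (is.null(ch$valid)) ch$valid <- rep(TRUE, length(ch$values))
    if (length(ch$valid) != length(ch$values)) {
      stop("channel '", role, "': valid mask length (", length(ch$valid),
           ") != values length (", length(ch$values), ")", call. = FALSE)
    }
    ch$valid <- ch$valid & !is.na(ch$values)
    if (role == "spo2") {
      ch$valid <- ch$valid & ch$values >= 0 & ch$values <= 100
    }
    if (role == "hr") {
      ch$valid <- ch$valid & ch$values > 0
    }
    ch[c("values", "rate", "valid")]
  })
  names(channels) <- roles
  structure(
    list(channels = channels, start_time = start_time,
         subject_id = as.character(subject_id)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> subject:", x$subject_id,
      " start:", x$start_time, "s\n")
  for (role in names(x$channels)) {
    ch <- x$channels[[role]]
    cat(sprintf("  %-5s %9d samples @ %g Hz (%.1f h), %.1f%% valid\n",
                role, length(ch$values), ch$rate,
                length(ch$values) / ch$rate / 3600,
                100 * mean(ch$valid)))
  }
  invisible(x)
}

#' Extract one channel of a recording
#'
#' @param rec a [recording()].
#' @param role channel role, e.g. `"resp"`, `"spo2"`, `"hr"`, `"ecg"`.
#' @return list with `values`, `rate`, `valid`.
#' @export
rec_channel <- function(rec, role) {
  stopifnot(inherits(rec, "recording"))
  ch <- rec$channels[[role]]
  if (is.null(ch)) {
    stop("recording has no '", role, "' channel (present: ",
         paste(names(rec$channels), collapse = ", "), ")", call. = FALSE)
  }
  ch
}

#' Add or replace a channel in a recording
#'
#' @inheritParams rec_channel
#' @param values numeric sample vector.
#' @param rate sampling rate, Hz.
#' @param valid logical validity mask (default all valid).
#' @return the modified `recording`.
#' @export
rec_set_channel <- function(rec, role, values, rate, valid = NULL) {
  stopifnot(inherits(rec, "recording"))
  ch <- list(values = values, rate = rate,
             valid = if (is.null(valid)) rep(TRUE, length(values)) else valid)
  rec$channels[[role]] <- ch
  # re-run construction-time validation
  recording(rec$channels, start_time = rec$start_time,
            subject_id = rec$subject_id)
}

#' Duration of a recording in seconds
#'
#' The span of the longest channel.
#' @inheritParams rec_channel
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  max(vapply(rec$channels,
             function(ch) length(ch$values) / ch$rate, numeric(1)))
}
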