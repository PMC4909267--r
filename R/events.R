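#' Event lists
#'
#' Detected physiological events are kept in a plain data frame of class
#' `event_list` with columns `subject_id`, `type` (one of `pause_short`,
#' `pause_long`, `desat`, `brady`), `threshold` (numeric; the SpO2 percent or
#' heart-rate bpm threshold that defines the episode, `NA` for pauses),
#' `onset` (seconds from recording start) and `duration` (seconds). After
#' [assign_events()] a `condition` column (`"ON"`/`"OFF"`) is present.
#'
#' @param type,threshold,onset,duration event fields (recycled to a common
#'   length).
#' @param subject_id subject identifier.
#' @param condition optional condition labels.
#' @return an `event_list` data frame sorted by onset.
#' @export
event_list <- function(type = character(), threshold = numeric(),
                       onset = numeric(), duration = numeric(),
                       subject_id = "subject", condition = NULL) {
  n <- max(length(type), length(onset), length(duration))
  if (n == 0L) {
    df <- data.frame(subject_id = character(), type = character(),
                     threshold = numeric(), onset = numeric(),
                     duration = numeric(), condition = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("event_list", "data.frame")
    return(df)
  }
  if (length(threshold) == 0L) threshold <- NA_real_
  df <- data.frame(
    subject_id = rep_len(as.character(subject_id), n),
    type = rep_len(as.character(type), n),
    threshold = rep_len(as.numeric(threshold), n),
    onset = rep_len(as.numeric(onset), n),
    duration = rep_len(as.numeric(duration), n),
    condition = rep_len(
      if (is.null(condition)) NA_character_ else as.character(condition), n),
    stringsAsFactors = FALSE
  )
  stopifnot(all(df$duration > 0))
  df <- df[order(df$onset, df$type, df$threshold), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_list", "data.frame")
  df
}

as_event_list <- function(df) {
  if (is.null(df$condition)) df$condition <- NA_character_
  if (is.null(df$threshold)) df$threshold <- NA_real_
  df <- df[order(df$onset, df$type, df$threshold), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("event_list", class(df)))
  df
}

#' Combine event lists
#' @param ... `event_list` objects.
#' @return a single `event_list` sorted by onset.
#' @export
bind_events <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0L) return(event_list())
  as_event_list(do.call(rbind, lapply(parts, as.data.frame)))
}

# Maximal runs of valid samples strictly below `threshold` lasting at least
# `min_dur` seconds. Invalid samples interrupt a run. Sample i sits at time
# start_time + (i-1)/rate; a run of L samples has duration L/rate.
threshold_runs <- function(x, valid, rate, threshold, min_dur,
                           start_time = 0) {
  stopifnot(length(x) == length(valid), rate > 0)
  below <- valid & !is.na(x) & (x < threshold)
  if (!any(below)) return(data.frame(onset = numeric(), duration = numeric()))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / rate >= min_dur)
  data.frame(onset = start_time + (starts[keep] - 1L) / rate,
             duration = r$lengths[keep] / rate)
}
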