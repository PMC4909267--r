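#' Stimulation schedule of 6-hour ON/OFF blocks
#'
#' The crossover design alternates stimulation ON and OFF in contiguous
#' blocks (default four 6-h blocks covering 24 h, i.e. 12 h per condition).
#'
#' @param order `"on_first"` or `"off_first"`.
#' @param block_hours block length, hours.
#' @param n_blocks number of blocks.
#' @param start schedule start time, seconds.
#' @return a `stim_schedule` data frame with columns `block`, `start`, `end`
#'   (seconds) and `condition` (`"ON"`/`"OFF"`), plus an `order` attribute.
#' @export
stim_schedule <- function(order = c("off_first", "on_first"),
                          block_hours = 6, n_blocks = 4, start = 0) {
  order <- match.arg(order)
  stopifnot(block_hours > 0, n_blocks >= 1)
  first <- if (order == "on_first") c("ON", "OFF") else c("OFF", "ON")
  cond <- rep_len(first, n_blocks)
  len <- block_hours * 3600
  s <- structure(
    data.frame(block = seq_len(n_blocks),
               start = start + (seq_len(n_blocks) - 1) * len,
               end = start + seq_len(n_blocks) * len,
               condition = cond,
               stringsAsFactors = FALSE),
    class = c("stim_schedule", "data.frame"))
  attr(s, "order") <- order
  s
}

schedule_span <- function(schedule) {
  c(min(schedule$start), max(schedule$end))
}

#' Label events with their stimulation condition
#'
#' Each event receives the condition of the block containing its onset;
#' events are never split or truncated at block boundaries (an episode that
#' starts just before a boundary belongs entirely to the earlier block). An
#' onset exactly at a boundary belongs to the later block.
#'
#' @param events an `event_list`.
#' @param schedule a [stim_schedule()].
#' @return the `event_list` with its `condition` column filled in.
#' @export
assign_events <- function(events, schedule) {
  stopifnot(inherits(schedule, "data.frame"))
  if (nrow(events) == 0L) return(events)
  span <- schedule_span(schedule)
  bad <- events$onset < span[1] | events$onset >= span[2]
  if (any(bad)) {
    stop("assign_events: ", sum(bad), " event onset(s) outside the schedule ",
         "span [", span[1], ", ", span[2], ") s", call. = FALSE)
  }
  i <- findInterval(events$onset, schedule$start)
  events$condition <- schedule$condition[i]
  events
}

outcome_levels <- function() {
  c("pause_short", "pause_long", "desat90", "desat88", "desat85",
    "brady110", "brady100")
}

# map (type, threshold) -> outcome key
event_outcome <- function(events) {
  ifelse(events$type %in% c("pause_short", "pause_long"), events$type,
         paste0(events$type,
                ifelse(is.na(events$threshold), "",
                       format(events$threshold, trim = TRUE))))
}

#' Per-subject, per-condition event totals
#'
#' Tallies counts and total durations of every outcome (short/long pauses,
#' desaturations below 90/88/85%, bradycardia below 110/100 bpm) under each
#' condition, together with the valid monitored time per condition computed
#' from a channel's validity mask. Totals (not rates) are the primary
#' output, matching how a crossover with equal 12-h exposure per condition
#' is analysed; valid time is carried so unequal artifact burden between
#' conditions can be checked.
#'
#' @param events a condition-labeled `event_list` (see [assign_events()]).
#' @param schedule the [stim_schedule()] used for labeling.
#' @param rec optional [recording()]; its `mask_channel` supplies the
#'   validity mask for monitored-time bookkeeping. Without a recording the
#'   full schedule time is taken as valid.
#' @param mask_channel channel role whose mask defines monitored time.
#' @param subject_id subject identifier (defaults to the one in `events` or
#'   `rec`).
#' @return a one-row `subject_summary` data frame with columns
#'   `subject_id`, `order`, `<outcome>_count_<on|off>`,
#'   `<outcome>_dur_<on|off>` and `valid_time_<on|off>` (seconds).
#' @export
summarize_subject <- function(events, schedule, rec = NULL,
                              mask_channel = "resp", subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- if (!is.null(rec)) rec$subject_id
                  else if (nrow(events) > 0) events$subject_id[1]
                  else "subject"
  }
  if (nrow(events) > 0 && anyNA(events$condition)) {
    stop("summarize_subject: events must be condition-labeled first ",
         "(see assign_events)", call. = FALSE)
  }
  row <- list(subject_id = subject_id,
              order = attr(schedule, "order") %||%
                (if (schedule$condition[1] == "ON") "on_first" else "off_first"))
  key <- if (nrow(events) > 0) event_outcome(events) else character()
  for (oc in outcome_levels()) {
    for (cond in c("on", "off")) {
      sel <- key == oc & events$condition == toupper(cond)
      row[[paste0(oc, "_count_", cond)]] <- sum(sel)
      row[[paste0(oc, "_dur_", cond)]] <- sum(events$duration[sel])
    }
  }
  vt <- valid_time_by_condition(schedule, rec, mask_channel)
  row$valid_time_on <- vt[["ON"]]
  row$valid_time_off <- vt[["OFF"]]
  out <- as.data.frame(row, stringsAsFactors = FALSE)
  class(out) <- c("subject_summary", "data.frame")
  out
}

valid_time_by_condition <- function(schedule, rec, mask_channel) {
  tot <- c(ON = 0, OFF = 0)
  if (is.null(rec)) {
    for (i in seq_len(nrow(schedule))) {
      cond <- schedule$condition[i]
      tot[cond] <- tot[cond] + (schedule$end[i] - schedule$start[i])
    }
    return(tot)
  }
  ch <- rec_channel(rec, mask_channel)
  tt <- rec$start_time + (seq_along(ch$values) - 1) / ch$rate
  for (i in seq_len(nrow(schedule))) {
    cond <- schedule$condition[i]
    sel <- tt >= schedule$start[i] & tt < schedule$end[i]
    tot[cond] <- tot[cond] + sum(ch$valid[sel]) / ch$rate
  }
  tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a
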