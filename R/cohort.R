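#' Study-scale calibration of the count-level cohort model
#'
#' Per-outcome no-stimulation means and ON/OFF ratios used by
#' [generate_cohort()]'s fast mode. Values are chosen to emulate a cohort in
#' which stimulation reduces long-pause counts by 39% (OFF mean ~282 per
#' 12 h), short pauses by 21%, IH episodes below 90% by 28% (30% of their
#' total duration), and bradycardia episodes roughly 3-fold. The <88% and
#' <85% IH thresholds share the <90% ratios (separate ratios for them are
#' not identified by the aggregate effects being emulated).
#'
#' @return data frame with columns `outcome`, `count_off`, `count_ratio`,
#'   `dur_off`, `dur_ratio`.
#' @export
cohort_calibration <- function() {
  data.frame(
    outcome = outcome_levels(),
    count_off = c(185.7, 282.1, 150.0, 100.0, 71.4, 63.0, 54.0),
    count_ratio = c(0.79, 0.61, 0.72, 0.72, 0.72, 1 / 3, 1 / 3),
    dur_off = c(830.0, 2147.2, 2786.7, 2183.3, 1480.0, 769.0, 666.0),
    dur_ratio = c(0.80, 0.64, 0.70, 0.70, 0.70, 185 / 769, 172 / 666),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort summary table
#'
#' Produces one row per subject with per-condition counts and total
#' durations for every outcome, with ON/OFF order randomized per subject by
#' coin flip.
#'
#' Two modes:
#' \describe{
#' \item{`"counts"`}{fast count-level model: a log-normal subject frailty
#'   multiplies every outcome's mean, counts are negative-binomial around
#'   the frailty-scaled mean (condition effect = the outcome's rate ratio),
#'   and total durations are count times a noisy per-event mean duration.}
#' \item{`"signal"`}{full simulation: each subject's 24-h recording is
#'   generated with [generate_recording()] (apnea rate scaled by the
#'   subject frailty), events are detected with [detect_events()], assigned
#'   to blocks and summarized — the complete pipeline end to end.}
#' }
#'
#' @param n_subjects number of subjects (>= 2); the emulated study analyzed
#'   15.
#' @param seed integer seed for the cohort-level generator; per-subject
#'   signal seeds are derived by fixed offsets.
#' @param mode `"counts"` or `"signal"`.
#' @param rate_ratio optional single ON/OFF ratio overriding every
#'   outcome's calibrated ratio (counts and per-event durations); use 1 for
#'   a null cohort.
#' @param calibration calibration table, see [cohort_calibration()].
#' @param sigma_u SD of the log-normal subject frailty (> 0).
#' @param nb_size negative-binomial size (within-subject dispersion) for
#'   counts mode.
#' @param sigma_d SD of the log-scale noise on per-event mean durations.
#' @param params a [sim_params()] used by signal mode.
#' @return a `cohort_table` data frame (one `subject_summary` row per
#'   subject).
#' @export
generate_cohort <- function(n_subjects = 15, seed = 1L,
                            mode = c("counts", "signal"),
                            rate_ratio = NULL,
                            calibration = cohort_calibration(),
                            sigma_u = 0.6, nb_size = 12, sigma_d = 0.15,
                            params = sim_params()) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 2)
  if (sigma_u <= 0) {
    stop("sigma_u must be > 0: the subject random effect is part of the ",
         "model; a degenerate (zero-variance) frailty is not supported",
         call. = FALSE)
  }
  rows <- with_seed(seed, {
    frailty <- exp(stats::rnorm(n_subjects, 0, sigma_u))
    order <- ifelse(stats::runif(n_subjects) < 0.5, "on_first", "off_first")
    if (mode == "counts") {
      lapply(seq_len(n_subjects), function(i) {
        cohort_counts_row(sprintf("S%02d", i), order[i], frailty[i],
                          calibration, rate_ratio, nb_size, sigma_d)
      })
    } else {
      sub_seeds <- params$seed + 1000L * seq_len(n_subjects)
      # in signal mode the frailty scales the apnea hazard; truncate it so
      # extreme draws stay within a physiologic (and feasible) apnea load
      sig_frailty <- pmin(pmax(frailty, 1 / 3), 2)
      lapply(seq_len(n_subjects), function(i) {
        p <- params
        p$seed <- sub_seeds[i]
        if (!is.null(rate_ratio)) p$stim_rate_ratio <- rate_ratio
        p$apnea_rate_off <- params$apnea_rate_off * sig_frailty[i]
        sched <- stim_schedule(order[i])
        gen <- generate_recording(p, sched,
                                  subject_id = sprintf("S%02d", i))
        ev <- detect_events(gen$recording)
        ev <- assign_events(ev, sched)
        summarize_subject(ev, sched, gen$recording)
      })
    }
  })
  cohort <- do.call(rbind, rows)
  class(cohort) <- c("cohort_table", "data.frame")
  validate_cohort(cohort)
}

cohort_counts_row <- function(sid, order, u, calibration, rate_ratio,
                              nb_size, sigma_d) {
  row <- list(subject_id = sid, order = order)
  for (j in seq_len(nrow(calibration))) {
    oc <- calibration$outcome[j]
    cr <- if (is.null(rate_ratio)) calibration$count_ratio[j] else rate_ratio
    dr_event <- if (is.null(rate_ratio)) {
      calibration$dur_ratio[j] / calibration$count_ratio[j]
    } else 1
    mu_off <- calibration$count_off[j] * u
    c_off <- stats::rnbinom(1, mu = mu_off, size = nb_size)
    c_on <- stats::rnbinom(1, mu = mu_off * cr, size = nb_size)
    per_ev <- calibration$dur_off[j] / calibration$count_off[j]
    d_off <- c_off * per_ev * exp(stats::rnorm(1, 0, sigma_d))
    d_on <- c_on * per_ev * dr_event * exp(stats::rnorm(1, 0, sigma_d))
    row[[paste0(oc, "_count_on")]] <- c_on
    row[[paste0(oc, "_count_off")]] <- c_off
    row[[paste0(oc, "_dur_on")]] <- d_on
    row[[paste0(oc, "_dur_off")]] <- d_off
  }
  row$valid_time_on <- 12 * 3600
  row$valid_time_off <- 12 * 3600
  as.data.frame(row, stringsAsFactors = FALSE)
}

# schema + invariant checks shared by the generator and the readers
validate_cohort <- function(cohort) {
  need <- cohort_columns()
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$subject_id)) {
    stop("duplicate subject id(s): ",
         paste(unique(cohort$subject_id[duplicated(cohort$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (nm in grep("_(count|dur)_(on|off)$", need, value = TRUE)) {
    v <- cohort[[nm]]
    if (any(!is.finite(v) | v < 0)) {
      stop("negative or non-finite values in column ", nm, call. = FALSE)
    }
    if (grepl("_count_", nm) && any(v != round(v))) {
      stop("non-integer counts in column ", nm, call. = FALSE)
    }
  }
  class(cohort) <- unique(c("cohort_table", class(cohort)))
  cohort
}

cohort_columns <- function() {
  oc <- outcome_levels()
  c("subject_id", "order",
    as.vector(t(outer(oc, c("_count_on", "_count_off", "_dur_on", "_dur_off"),
                      paste0))),
    "valid_time_on", "valid_time_off")
}
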