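#' Build a run configuration
#'
#' Collects the knobs of an end-to-end run: input location and format,
#' schedule definition, detection thresholds (defaults as in the emulated
#' study: pauses >3--5 s / >5 s, SpO2 below 90/88/85% for >= 5 s,
#' bradycardia below 110/100 bpm), transform and significance level, seed
#' and output directory. Settings may come from a YAML/JSON file with the
#' same field names; explicit arguments override file values.
#'
#' @param file optional YAML or JSON config file.
#' @param ... overrides of individual fields (`input`, `format`,
#'   `channel_map`, `subject_id`, `schedule_order`, `block_hours`,
#'   `n_blocks`, `pause_short`, `pause_long`, `spo2_thresholds`,
#'   `desat_min_dur`, `brady_thresholds`, `brady_min_dur`, `spo2_window`,
#'   `transform`, `alpha`, `seed`, `out_dir`, `n_subjects`, `sim`).
#' @return a `run_config` list.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    input = NULL, format = "auto", channel_map = NULL, subject_id = NULL,
    schedule_order = "off_first", block_hours = 6, n_blocks = 4,
    pause_short = 3, pause_long = 5,
    spo2_thresholds = c(90, 88, 85), desat_min_dur = 5,
    brady_thresholds = c(110, 100), brady_min_dur = 1,
    spo2_window = NULL,
    transform = "lnp1", alpha = 0.05, seed = 1L, out_dir = ".",
    n_subjects = 15, sim = list()
  )
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    loaded <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML configs require the yaml package", call. = FALSE)
      }
      yaml::read_yaml(file)
    } else {
      jsonlite::fromJSON(file, simplifyVector = TRUE)
    }
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$block_hours > 0, cfg$pause_short > 0,
            cfg$pause_long >= cfg$pause_short,
            all(cfg$spo2_thresholds > 0), all(cfg$brady_thresholds > 0))
  class(cfg) <- "run_config"
  cfg
}

config_schedule <- function(cfg) {
  stim_schedule(cfg$schedule_order, block_hours = cfg$block_hours,
                n_blocks = cfg$n_blocks)
}

write_manifest <- function(out_dir, cfg, extra = list()) {
  cfg_plain <- unclass(cfg)
  # the hash identifies the analytic configuration; where outputs land is
  # not part of it
  cfg_hashable <- cfg_plain[setdiff(names(cfg_plain), "out_dir")]
  cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- c(list(
    package = "neoapnea",
    version = as.character(utils::packageVersion("neoapnea")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    config = cfg_plain
  ), extra)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

run_log <- function(...) message("[neoapnea] ", ...)

#' Detect and summarize events for one recording
#'
#' End-to-end detection stage: read the recording, derive heart rate from
#' ECG when no HR channel is present, run all detectors, label events with
#' their schedule condition, and write `events.csv`, a one-row
#' `summary.csv` and a reproducibility manifest to the output directory.
#'
#' @param cfg a [run_config()] with `input` set (path to EDF or CSV
#'   bundle).
#' @return invisibly, a list with `events` and `summary`.
#' @export
run_detect <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$input)) {
    stop("run_detect: config field 'input' is not set", call. = FALSE)
  }
  rec <- read_recording(cfg$input, format = cfg$format,
                        channel_map = cfg$channel_map)
  if (!is.null(cfg$subject_id)) rec$subject_id <- cfg$subject_id
  schedule <- config_schedule(cfg)
  run_log("read ", cfg$input, ": ", length(rec$channels), " channels")
  events <- detect_events(
    rec,
    pause_bounds = c(cfg$pause_short, cfg$pause_long),
    spo2_thresholds = cfg$spo2_thresholds,
    desat_min_dur = cfg$desat_min_dur,
    brady_thresholds = cfg$brady_thresholds,
    brady_min_dur = cfg$brady_min_dur,
    spo2_window = cfg$spo2_window)
  run_log("detected ", nrow(events), " events (",
          sum(grepl("pause", events$type)), " pauses, ",
          sum(events$type == "desat"), " desats, ",
          sum(events$type == "brady"), " bradys)")
  events <- assign_events(events, schedule)
  summary <- summarize_subject(events, schedule, rec)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_events(events, file.path(cfg$out_dir, "events.csv"))
  utils::write.csv(as.data.frame(summary),
                   file.path(cfg$out_dir, "summary.csv"), row.names = FALSE)
  write_manifest(cfg$out_dir, cfg, list(stage = "detect",
                                        n_events = nrow(events)))
  invisible(list(events = events, summary = summary))
}

#' Cohort statistics stage
#'
#' Reads a cohort table, runs the full paired analysis
#' ([cohort_report()]) and the per-subject percent-change table
#' ([percent_change_table()]), and writes `report.csv`,
#' `percent_change.csv`, a human-readable `report.md` and a manifest.
#'
#' @param cfg a [run_config()].
#' @param cohort_path cohort table (CSV/XLSX); may also be a
#'   `cohort_table` object.
#' @param col_map passed to [read_cohort_table()].
#' @return invisibly, a list with `report` and `percent_change`.
#' @export
run_stats <- function(cfg, cohort_path, col_map = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- if (is.character(cohort_path)) {
    read_cohort_table(cohort_path, col_map = col_map)
  } else {
    validate_cohort(cohort_path)
  }
  report <- cohort_report(cohort, transform = cfg$transform,
                          alpha = cfg$alpha)
  pct <- percent_change_table(cohort)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report),
                   file.path(cfg$out_dir, "report.csv"), row.names = FALSE)
  utils::write.csv(pct, file.path(cfg$out_dir, "percent_change.csv"),
                   row.names = FALSE)
  md <- utils::capture.output(print(report))
  writeLines(c("# Paired crossover report", "", "```", md, "```"),
             file.path(cfg$out_dir, "report.md"))
  write_manifest(cfg$out_dir, cfg,
                 list(stage = "stats", n_subjects = nrow(cohort)))
  run_log("report written for ", nrow(cohort), " subjects, ",
          sum(report$significant), "/", nrow(report),
          " outcomes significant at alpha = ", cfg$alpha)
  invisible(list(report = report, percent_change = pct))
}

#' Simulation campaign stage
#'
#' Generates a synthetic cohort (and optionally the underlying recordings
#' with their ground truth) and writes `cohort.csv`, per-subject ground
#' truth event CSVs, and a manifest with all seeds.
#'
#' @param cfg a [run_config()]; `cfg$sim` entries override [sim_params()]
#'   fields, `cfg$n_subjects` sets the cohort size.
#' @param mode passed to [generate_cohort()].
#' @param write_recordings also write each subject's signals as a CSV
#'   bundle (sizeable; off by default).
#' @return invisibly, the cohort table.
#' @export
run_simulate <- function(cfg, mode = c("counts", "signal"),
                         write_recordings = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  mode <- match.arg(mode)
  params <- do.call(sim_params, c(cfg$sim, list(seed = cfg$seed)))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cfg$n_subjects, seed = cfg$seed, mode = mode,
                            params = params)
  write_cohort_table(cohort, file.path(cfg$out_dir, "cohort.csv"))
  if (mode == "signal" && write_recordings) {
    for (i in seq_len(cfg$n_subjects)) {
      p <- params
      p$seed <- params$seed + 1000L * i
      gen <- generate_recording(p, config_schedule(cfg),
                                subject_id = sprintf("S%02d", i))
      write_csv_bundle(gen$recording,
                       file.path(cfg$out_dir, sprintf("S%02d_signals", i)))
    }
  }
  write_manifest(cfg$out_dir, cfg,
                 list(stage = "simulate", mode = mode,
                      subject_seeds = params$seed +
                        1000L * seq_len(cfg$n_subjects)))
  run_log("simulated cohort of ", cfg$n_subjects, " subjects (", mode,
          " mode)")
  invisible(cohort)
}
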