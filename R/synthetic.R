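#' Simulation parameters for synthetic neonatal recordings
#'
#' Defaults emulate the study conditions of a 24-h NICU crossover recording
#' in a preterm infant with apnea of prematurity: quasi-periodic breathing at
#' 55 breaths/min, apneic pauses as a point process whose rate drops by the
#' stimulation rate ratio during ON blocks, and the downstream cascade of a
#' pause — a lagged desaturation (oximeter-averaged over 8 s) and an earlier,
#' deeper heart-rate slowing. Baseline heart rate sits in the 150--165 bpm
#' band typical of this population; a 13-s pause with the default coupling
#' slopes produces bradycardia below 80 bpm and a desaturation below 90%
#' lasting on the order of 25 s.
#'
#' @param duration_h recording length, hours.
#' @param resp_rate respiratory-effort (and ECG) sampling rate, Hz.
#' @param vitals_rate SpO2/HR trend sampling rate, Hz (monitors emit ~1 Hz).
#' @param breath_rate baseline breathing rate, breaths/min.
#' @param breath_amp effort amplitude, arbitrary units.
#' @param breath_jitter_sd SD of per-breath period jitter, s (0 = strictly
#'   periodic).
#' @param breath_amp_jitter SD of per-breath relative amplitude jitter.
#' @param apnea_rate_off apnea rate during OFF (no-stimulation) blocks,
#'   events/h.
#' @param pause_meanlog,pause_sdlog log-normal parameters of pause
#'   durations, s.
#' @param pause_max cap on a single pause duration, s.
#' @param stim_rate_ratio multiplicative hazard ratio applied to the apnea
#'   rate during ON blocks (0.61 corresponds to a 39% reduction).
#' @param min_separation enforced gap between the end of one pause and the
#'   onset of the next, s (keeps ground truth unambiguous).
#' @param baseline_hr baseline heart rate, bpm.
#' @param baseline_spo2 baseline oxygen saturation, %.
#' @param desat_lag delay from pause onset to the start of the SpO2
#'   deflection, s.
#' @param desat_slope desaturation depth per second of pause, %/s.
#' @param desat_floor saturation floor, %.
#' @param desat_recovery extra width of the desaturation deflection beyond
#'   twice the pause duration, s.
#' @param brady_lag delay from pause onset to the heart-rate deflection, s
#'   (bradycardia precedes the desaturation).
#' @param brady_slope heart-rate deflection depth per second of pause,
#'   bpm/s.
#' @param brady_floor heart-rate floor, bpm.
#' @param brady_recovery extra width of the heart-rate deflection beyond the
#'   pause duration, s.
#' @param spo2_window oximeter averaging time applied by the observation
#'   model, s.
#' @param noise_sd named vector of per-channel measurement-noise SDs
#'   (`resp` in effort units, `spo2` in %, `hr` in bpm). Set all to 0 (with
#'   `breath_jitter_sd = 0`) for a fully deterministic, noise-free record.
#' @param include_ecg also synthesize an ECG impulse train consistent with
#'   the heart-rate channel.
#' @param seed integer seed; a fixed seed makes the output bit-reproducible.
#' @return a `sim_params` list.
#' @export
sim_params <- function(duration_h = 24, resp_rate = 250, vitals_rate = 1,
                       breath_rate = 55, breath_amp = 1,
                       breath_jitter_sd = 0.05, breath_amp_jitter = 0.1,
                       apnea_rate_off = 40, pause_meanlog = log(5.5),
                       pause_sdlog = 0.5, pause_max = 60,
                       stim_rate_ratio = 0.61, min_separation = 30,
                       baseline_hr = 157, baseline_spo2 = 96,
                       desat_lag = 8, desat_slope = 1.2, desat_floor = 75,
                       desat_recovery = 15,
                       brady_lag = 4, brady_slope = 6, brady_floor = 70,
                       brady_recovery = 10, spo2_window = 8,
                       noise_sd = c(resp = 0.05, spo2 = 0.3, hr = 1),
                       include_ecg = FALSE, seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$duration_h > 0, p$resp_rate > 0, p$vitals_rate > 0,
            p$breath_rate > 0, p$apnea_rate_off >= 0,
            p$stim_rate_ratio > 0,
            p$baseline_hr > 0, p$baseline_hr < 300,
            p$baseline_spo2 > 0, p$baseline_spo2 <= 100,
            all(p$noise_sd >= 0))
  for (nm in c("resp", "spo2", "hr")) {
    if (is.null(names(p$noise_sd)) || !nm %in% names(p$noise_sd)) {
      if (length(p$noise_sd) == 1L && is.null(names(p$noise_sd))) {
        p$noise_sd <- c(resp = unname(p$noise_sd), spo2 = unname(p$noise_sd),
                        hr = unname(p$noise_sd))
      } else {
        stop("noise_sd must be named with resp, spo2 and hr", call. = FALSE)
      }
    }
  }
  class(p) <- "sim_params"
  p
}

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# `seed` is forced first: if it is itself drawn from the caller's RNG, that
# draw must happen before the state is captured.
with_seed <- function(seed, code) {
  force(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample the apnea event plan for a schedule
#'
#' Draws pause onsets and durations block by block as a renewal process:
#' after each pause the process waits out the enforced minimum separation and
#' then an exponential time whose rate is adjusted for the dead time, so the
#' requested hourly rate is attained despite the refractory gap. During ON
#' blocks the rate is multiplied by `stim_rate_ratio`. Operates purely at
#' the event level (no waveforms), so it is cheap enough for Monte-Carlo
#' studies of rate recovery.
#'
#' @param params a [sim_params()].
#' @param schedule a [stim_schedule()] covering the recording.
#' @param settle do not place pauses in the first/last this many seconds.
#' @return data frame with `onset`, `duration` (drawn, s) and `condition`.
#' @export
simulate_event_plan <- function(params, schedule,
                                settle = 60) {
  stopifnot(inherits(params, "sim_params"))
  span <- schedule_span(schedule)
  if (params$duration_h * 3600 > span[2] - span[1] + 1e-9) {
    stop("schedule does not cover the recording duration", call. = FALSE)
  }
  mean_d <- min(exp(params$pause_meanlog + params$pause_sdlog^2 / 2),
                params$pause_max)
  dead <- params$min_separation + mean_d
  t_end_all <- span[2] - max(settle, 120)
  onset <- duration <- numeric(0)
  cond <- character(0)
  cursor <- span[1] + settle
  for (i in seq_len(nrow(schedule))) {
    lam <- params$apnea_rate_off / 3600 *
      if (schedule$condition[i] == "ON") params$stim_rate_ratio else 1
    if (lam <= 0) next
    if (lam * dead >= 0.9) {
      stop("infeasible apnea parameters: expected apnea + refractory time ",
           "exceeds block time", call. = FALSE)
    }
    lam_adj <- lam / (1 - lam * dead)
    cursor <- max(cursor, schedule$start[i])
    repeat {
      t0 <- cursor + stats::rexp(1, lam_adj)
      if (t0 >= schedule$end[i] || t0 >= t_end_all) {
        cursor <- max(cursor, min(schedule$end[i], t_end_all))
        break
      }
      d <- min(stats::rlnorm(1, params$pause_meanlog, params$pause_sdlog),
               params$pause_max)
      onset <- c(onset, t0)
      duration <- c(duration, d)
      cond <- c(cond, schedule$condition[i])
      cursor <- t0 + d + params$min_separation
    }
  }
  data.frame(onset = onset, duration = duration, condition = cond,
             stringsAsFactors = FALSE)
}

classify_pause <- function(d, short_min = 3, short_max = 5) {
  ifelse(d > short_max, "pause_long",
         ifelse(d > short_min, "pause_short", NA_character_))
}

# raised-cosine deflection of `depth` over support [t0, t0 + width],
# accumulated onto `values` sampled at `rate` starting at time 0
add_pulse <- function(values, rate, t0, width, depth) {
  n <- length(values)
  i0 <- max(1L, floor(t0 * rate) + 1L)
  i1 <- min(n, ceiling((t0 + width) * rate) + 1L)
  if (i1 < i0) return(values)
  tt <- (seq(i0, i1) - 1) / rate
  s <- (tt - t0) / width
  inside <- s >= 0 & s <= 1
  values[seq(i0, i1)][inside] <- values[seq(i0, i1)][inside] +
    depth * 0.5 * (1 - cos(2 * pi * s[inside]))
  values
}

#' Generate a synthetic cardiorespiratory recording with ground truth
#'
#' Builds a labeled multichannel record: a quasi-periodic respiratory effort
#' waveform silenced during apneic pauses sampled by
#' [simulate_event_plan()]; a true SpO2 trace with lagged, pause-scaled
#' raised-cosine desaturations observed through the oximeter model (trailing
#' moving average over `spo2_window` seconds, see [smooth_spo2()]); a
#' heart-rate trace with earlier, pause-scaled decelerations; and optionally
#' an ECG impulse train consistent with the heart rate. Measurement noise is
#' added per channel after the deterministic physiology is laid down, so the
#' ground truth lists the events implied by the noiseless record.
#'
#' Pause onsets are snapped to the breath grid; the realized pause duration
#' (the silent time beyond one nominal cycle actually present in the
#' waveform) is what the ground truth reports, and realized durations within
#' 0.1 s of the 3-s/5-s class boundaries are extended slightly so the
#' short/long classification is unambiguous at the detector's peak-timing
#' resolution.
#'
#' @param params a [sim_params()].
#' @param schedule a [stim_schedule()]; defaults to four 6-h blocks,
#'   OFF-first.
#' @param subject_id subject identifier stored in the recording.
#' @return list with elements `recording` (a [recording()]), `truth` (class
#'   `ground_truth`: data frames `pauses`, `desat`, `brady`), and
#'   `schedule`.
#' @export
generate_recording <- function(params = sim_params(),
                               schedule = stim_schedule("off_first"),
                               subject_id = "synthetic") {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    T_s <- params$duration_h * 3600
    P <- 60 / params$breath_rate
    plan <- simulate_event_plan(params, schedule)

    # breath-onset grid with period jitter
    n_breath <- ceiling(T_s / P) + 16L
    gaps <- P + stats::rnorm(n_breath, 0, params$breath_jitter_sd)
    gaps <- pmax(gaps, 0.4 * P)
    bt <- cumsum(c(P, gaps))
    bt <- bt[bt < T_s - P]

    # carve pauses out of the breath grid; record realized durations
    keep <- rep(TRUE, length(bt))
    tr_onset <- tr_dur <- numeric(nrow(plan))
    tr_cond <- character(nrow(plan))
    eps <- 0.1
    for (j in seq_len(nrow(plan))) {
      d <- plan$duration[j]
      i0 <- findInterval(plan$onset[j], bt) + 1L   # first onset >= plan onset
      if (i0 > length(bt) || i0 <= 1L) { tr_dur[j] <- NA; next }
      repeat {
        drop <- which(bt >= bt[i0] & bt < bt[i0] + d)
        inext <- max(drop) + 1L
        if (inext > length(bt)) { realized <- NA; break }
        realized <- (bt[inext] - bt[i0 - 1L]) - P
        if (min(abs(realized - c(3, 5))) > eps) break
        d <- d + 0.1
      }
      if (is.na(realized)) { tr_dur[j] <- NA; next }
      keep[drop] <- FALSE
      tr_onset[j] <- bt[i0 - 1L] + P
      tr_dur[j] <- realized
      tr_cond[j] <- plan$condition[j]
    }
    ok <- !is.na(tr_dur)
    pauses <- data.frame(onset = tr_onset[ok], duration = tr_dur[ok],
                         type = classify_pause(tr_dur[ok]),
                         condition = tr_cond[ok], stringsAsFactors = FALSE)
    bt_kept <- bt[keep]

    # respiratory effort: one sinusoidal cycle per retained breath
    n_r <- round(T_s * params$resp_rate)
    tt <- (seq_len(n_r) - 1) / params$resp_rate
    amp <- params$breath_amp *
      pmin(pmax(1 + params$breath_amp_jitter *
                  stats::rnorm(length(bt_kept)), 0.5), 1.5)
    idx <- findInterval(tt, bt_kept)
    gap_next <- c(diff(bt_kept), Inf)
    resp <- numeric(n_r)
    inb <- idx >= 1L
    dt <- tt[inb] - bt_kept[idx[inb]]
    active <- dt < pmin(P, gap_next[idx[inb]])
    resp_in <- numeric(sum(inb))
    resp_in[active] <- amp[idx[inb]][active] *
      sin(2 * pi * dt[active] / P)
    resp[inb] <- resp_in
    resp <- resp + stats::rnorm(n_r, 0, params$noise_sd[["resp"]])

    # vitals: deterministic physiology, then observation model, then noise
    n_v <- round(T_s * params$vitals_rate)
    defl_spo2 <- numeric(n_v)
    defl_hr <- numeric(n_v)
    for (j in seq_len(nrow(pauses))) {
      d <- pauses$duration[j]
      defl_spo2 <- add_pulse(defl_spo2, params$vitals_rate,
                             pauses$onset[j] + params$desat_lag,
                             2 * d + params$desat_recovery,
                             min(params$desat_slope * d,
                                 params$baseline_spo2 - params$desat_floor))
      defl_hr <- add_pulse(defl_hr, params$vitals_rate,
                           pauses$onset[j] + params$brady_lag,
                           d + params$brady_recovery,
                           min(params$brady_slope * d,
                               params$baseline_hr - params$brady_floor))
    }
    spo2_true <- pmax(params$baseline_spo2 - defl_spo2, params$desat_floor)
    hr_true <- pmax(params$baseline_hr - defl_hr, params$brady_floor)

    spo2_det <- smooth_spo2(spo2_true, window = params$spo2_window,
                            rate = params$vitals_rate)$values
    truth_desat <- do.call(rbind, lapply(c(90, 88, 85), function(thr) {
      r <- threshold_runs(spo2_det, rep(TRUE, n_v), params$vitals_rate,
                          thr, min_dur = 5)
      if (nrow(r) == 0L) return(NULL)
      cbind(threshold = thr, r)
    }))
    truth_brady <- do.call(rbind, lapply(c(110, 100), function(thr) {
      r <- threshold_runs(hr_true, rep(TRUE, n_v), params$vitals_rate,
                          thr, min_dur = 1)
      if (nrow(r) == 0L) return(NULL)
      cbind(threshold = thr, r)
    }))
    empty_tr <- data.frame(threshold = numeric(), onset = numeric(),
                           duration = numeric())
    if (is.null(truth_desat)) truth_desat <- empty_tr
    if (is.null(truth_brady)) truth_brady <- empty_tr

    spo2_obs <- smooth_spo2(
      spo2_true + stats::rnorm(n_v, 0, params$noise_sd[["spo2"]]),
      window = params$spo2_window, rate = params$vitals_rate)$values
    spo2_obs <- pmin(pmax(spo2_obs, 0), 100)
    hr_obs <- hr_true + stats::rnorm(n_v, 0, params$noise_sd[["hr"]])

    channels <- list(
      resp = list(values = resp, rate = params$resp_rate),
      spo2 = list(values = spo2_obs, rate = params$vitals_rate),
      hr = list(values = hr_obs, rate = params$vitals_rate)
    )
    if (params$include_ecg) {
      channels$ecg <- list(values = render_ecg(hr_obs, params$resp_rate, T_s),
                           rate = params$resp_rate)
    }
    rec <- recording(channels, start_time = 0, subject_id = subject_id)
    truth <- structure(
      list(pauses = pauses[!is.na(pauses$type), , drop = FALSE],
           desat = truth_desat, brady = truth_brady,
           breaths = bt_kept),
      class = "ground_truth")
    list(recording = rec, truth = truth, schedule = schedule)
  })
}

# ECG as a train of narrow Gaussian R waves whose RR tracks the 1-Hz HR
render_ecg <- function(hr_1hz, rate, T_s) {
  beats <- numeric(ceiling(max(hr_1hz, na.rm = TRUE) / 60 * T_s) + 8L)
  t <- 0.3
  k <- 0L
  nh <- length(hr_1hz)
  while (t < T_s) {
    k <- k + 1L
    beats[k] <- t
    hr_now <- hr_1hz[min(nh, floor(t) + 1L)]
    if (!is.finite(hr_now) || hr_now <= 0) hr_now <- 120
    t <- t + 60 / hr_now
  }
  beats <- beats[seq_len(k)]
  ecg <- numeric(round(T_s * rate))
  ctr <- round(beats * rate) + 1L
  half <- max(2L, round(0.01 * rate))
  for (off in -half:half) {
    i <- ctr + off
    sel <- i >= 1L & i <= length(ecg)
    ecg[i[sel]] <- ecg[i[sel]] + exp(-0.5 * (off / (half / 2.5))^2)
  }
  ecg
}
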