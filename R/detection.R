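#' Detect breaths in a respiratory effort signal
#'
#' Breath markers are found by peak-to-peak cycle detection on a band-passed
#' effort signal. The channel is zero-filled over invalid samples, band-pass
#' filtered (Butterworth, zero phase), and local maxima are screened with an
#' adaptive amplitude threshold: a peak counts as a breath only if its height
#' exceeds `min_frac` times the rolling median height of neighbouring peaks
#' (floored at half the record-wide median so long apneic stretches of
#' low-level noise cannot drag the reference down).
#'
#' @param rec a [recording()] with a respiratory effort channel.
#' @param channel channel role holding respiratory effort.
#' @param band band-pass corner frequencies in Hz; the default 0.3--2.5 Hz
#'   spans neonatal breathing rates of 18--150 breaths/min.
#' @param min_frac fraction of the reference peak amplitude a local maximum
#'   must reach to count as a breath.
#' @param med_peaks number of neighbouring peaks in the rolling-median
#'   amplitude reference (rounded up to odd).
#' @param work_rate internal analysis rate, Hz. Effort sampled faster than
#'   this is decimated by block averaging first: the breathing band ends at
#'   `band[2]`, so ~10x oversampling preserves peak timing to a few tens of
#'   milliseconds while cutting filtering cost an order of magnitude.
#' @return a `breath_series` data frame with columns `onset` (s) and
#'   `amplitude` (a.u.), onsets strictly increasing.
#' @export
detect_breaths <- function(rec, channel = "resp", band = c(0.3, 2.5),
                           min_frac = 0.3, med_peaks = 101,
                           work_rate = 25) {
  ch <- rec_channel(rec, channel)
  rate <- ch$rate
  if (sum(ch$valid) / rate < 10) {
    stop("detect_breaths: fewer than 10 s of valid respiratory signal",
         call. = FALSE)
  }
  x <- ch$values
  x[!ch$valid] <- 0
  valid <- ch$valid
  fac <- floor(rate / work_rate)
  if (fac > 1) {
    n_full <- (length(x) %/% fac) * fac
    x <- colMeans(matrix(x[seq_len(n_full)], nrow = fac))
    vfrac <- colMeans(matrix(as.numeric(valid[seq_len(n_full)]),
                             nrow = fac))
    valid <- vfrac >= 0.5
    rate <- rate / fac
  }
  x <- x - stats::median(x[valid])
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)

  # strict local maxima above zero
  n <- length(xf)
  if (n < 3L) stop("detect_breaths: signal too short", call. = FALSE)
  core <- xf[2:(n - 1L)]
  is_peak <- core > xf[1:(n - 2L)] & core >= xf[3:n] & core > 0
  idx <- which(is_peak) + 1L
  idx <- idx[valid[idx]]
  if (length(idx) == 0L) {
    return(structure(data.frame(onset = numeric(), amplitude = numeric()),
                     class = c("breath_series", "data.frame")))
  }

  # refractory: no two candidate peaks closer than the fastest breath period,
  # keeping the taller one
  min_sep <- round(rate / band[2])
  keep <- keep_spaced_peaks(idx, xf[idx], min_sep)
  idx <- idx[keep]
  h <- xf[idx]

  # adaptive amplitude threshold
  k <- min(length(h), med_peaks)
  if (k %% 2L == 0L) k <- k - 1L
  ref <- if (k >= 3L) stats::runmed(h, k, endrule = "median") else h
  ref <- pmax(ref, 0.5 * stats::median(h))
  sel <- h >= min_frac * ref
  structure(
    data.frame(onset = rec$start_time + (idx[sel] - 1L) / rate,
               amplitude = h[sel]),
    class = c("breath_series", "data.frame")
  )
}

# Greedy refractory filter over candidate peak indices (sorted): within
# min_sep samples, only the tallest survives.
keep_spaced_peaks <- function(idx, height, min_sep) {
  m <- length(idx)
  if (m <= 1L) return(rep(TRUE, m))
  keep <- rep(TRUE, m)
  last <- 1L
  for (i in 2L:m) {
    if (idx[i] - idx[last] < min_sep) {
      if (height[i] > height[last]) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
  }
  keep
}

#' Detect breathing pauses from a breath series
#'
#' A pause is the silent time in an inter-breath interval beyond one expected
#' breathing cycle: for consecutive breath onsets the pause duration is
#' `interval - median breath period`, clipped at zero. This deliberately does
#' not count normal slow breaths as pauses. Pauses with duration `d`
#' satisfying `short_min < d <= short_max` are short pauses; `d > long_min`
#' are long pauses (with the defaults the two classes partition d > 3 s, and
#' a 5.0-s pause is short). The pause onset is placed one median period after
#' the last breath onset.
#'
#' @param breaths a `breath_series` from [detect_breaths()], or a numeric
#'   vector of breath onset times in seconds.
#' @param short_min,short_max short-pause bounds, seconds (exclusive lower,
#'   inclusive upper).
#' @param long_min long pauses are `d > long_min` seconds.
#' @param subject_id subject identifier for the returned events.
#' @return an `event_list` of `pause_short` / `pause_long` events.
#' @export
detect_pauses <- function(breaths, short_min = 3, short_max = 5,
                          long_min = 5, subject_id = "subject") {
  onsets <- if (is.data.frame(breaths)) breaths$onset else as.numeric(breaths)
  if (length(onsets) < 2L) return(event_list(subject_id = subject_id))
  stopifnot(!is.unsorted(onsets, strictly = TRUE))
  gaps <- diff(onsets)
  med <- stats::median(gaps)
  d <- gaps - med
  short <- d > short_min & d <= short_max
  long <- d > long_min
  type <- ifelse(long, "pause_long", ifelse(short, "pause_short", NA))
  sel <- !is.na(type)
  event_list(type = type[sel], threshold = NA_real_,
             onset = onsets[-length(onsets)][sel] + med,
             duration = d[sel], subject_id = subject_id)
}

#' Trailing moving-average (pulse-oximeter) smoothing of SpO2
#'
#' Causal boxcar average emulating a pulse oximeter's averaging time: the
#' output at sample *i* is the mean of the valid samples in the trailing
#' window of `window` seconds ending at *i* (inclusive). Invalid samples are
#' excluded from the average; where the window contains no valid sample the
#' output is marked invalid.
#'
#' @param spo2 a channel list (`values`, `rate`, `valid`) as returned by
#'   [rec_channel()], or a numeric vector (then `rate` must be given).
#' @param window averaging time, seconds (> 0). Default 8 s, the averaging
#'   time of the study oximeters.
#' @param rate sampling rate in Hz when `spo2` is a bare numeric vector.
#' @return a channel list with smoothed `values`, the same `rate`, and the
#'   derived `valid` mask.
#' @export
smooth_spo2 <- function(spo2, window = 8, rate = NULL) {
  stopifnot(window > 0)
  if (is.numeric(spo2)) {
    stopifnot(!is.null(rate))
    spo2 <- list(values = spo2, rate = rate,
                 valid = !is.na(spo2))
  }
  x <- spo2$values
  v <- spo2$valid & !is.na(x)
  k <- max(1L, round(window * spo2$rate))
  xz <- ifelse(v, x, 0)
  csum <- cumsum(xz)
  cnum <- cumsum(as.numeric(v))
  n <- length(x)
  if (k >= n) {
    lag <- rep(0, n)
    lagn <- rep(0, n)
  } else {
    lag <- c(rep(0, k), csum[seq_len(n - k)])
    lagn <- c(rep(0, k), cnum[seq_len(n - k)])
  }
  wsum <- csum - lag
  wnum <- cnum - lagn
  out <- ifelse(wnum > 0, wsum / wnum, NA_real_)
  list(values = out, rate = spo2$rate, valid = wnum > 0)
}

#' Detect intermittent-hypoxia (desaturation) episodes
#'
#' For each SpO2 threshold independently, maximal runs of valid samples
#' strictly below the threshold lasting at least `min_dur` seconds become one
#' desaturation event each; a sample equal to the threshold ends an episode.
#' Runs separated by any recovery sample are distinct events unless
#' `merge_gap > 0`, in which case consecutive runs separated by less than
#' `merge_gap` seconds are merged (duration then spans the merged extent).
#'
#' @param spo2 SpO2 channel (already at the oximeter's averaging time; apply
#'   [smooth_spo2()] first for raw beat-to-beat saturation), as a channel
#'   list or numeric vector with `rate`.
#' @param thresholds SpO2 thresholds in percent.
#' @param min_dur minimum episode duration, seconds.
#' @param merge_gap merge runs separated by less than this many seconds
#'   (default 0: no merging).
#' @param rate sampling rate when `spo2` is a bare vector.
#' @param subject_id subject identifier.
#' @param start_time time of the first sample, seconds.
#' @return an `event_list` of `desat` events labeled by threshold.
#' @export
detect_desaturations <- function(spo2, thresholds = c(90, 88, 85),
                                 min_dur = 5, merge_gap = 0, rate = NULL,
                                 subject_id = "subject", start_time = 0) {
  if (is.numeric(spo2)) {
    stopifnot(!is.null(rate))
    spo2 <- list(values = spo2, rate = rate, valid = !is.na(spo2))
  }
  run_detector(spo2, thresholds, min_dur, merge_gap,
               type = "desat", subject_id = subject_id,
               start_time = start_time)
}

#' Detect bradycardia episodes
#'
#' Per heart-rate threshold, maximal runs of valid samples strictly below the
#' threshold lasting at least `min_dur` seconds become bradycardia events.
#' The default minimum duration of 1 s suppresses single-sample artifacts.
#'
#' @param hr heart-rate channel (bpm), as a channel list or numeric vector
#'   with `rate`.
#' @param thresholds bpm thresholds; defaults 110 (mild) and 100 (moderate).
#' @param min_dur minimum episode duration, seconds.
#' @param merge_gap merge runs separated by less than this many seconds.
#' @param rate sampling rate when `hr` is a bare vector.
#' @param subject_id subject identifier.
#' @param start_time time of the first sample, seconds.
#' @return an `event_list` of `brady` events labeled by threshold.
#' @export
detect_bradycardia <- function(hr, thresholds = c(110, 100), min_dur = 1,
                               merge_gap = 0, rate = NULL,
                               subject_id = "subject", start_time = 0) {
  if (is.numeric(hr)) {
    stopifnot(!is.null(rate))
    hr <- list(values = hr, rate = rate, valid = !is.na(hr))
  }
  run_detector(hr, thresholds, min_dur, merge_gap,
               type = "brady", subject_id = subject_id,
               start_time = start_time)
}

run_detector <- function(ch, thresholds, min_dur, merge_gap, type,
                         subject_id, start_time) {
  out <- lapply(thresholds, function(thr) {
    runs <- threshold_runs(ch$values, ch$valid, ch$rate, thr,
                           min_dur = 0, start_time = start_time)
    if (merge_gap > 0 && nrow(runs) > 1L) {
      runs <- merge_runs(runs, merge_gap)
    }
    runs <- runs[runs$duration >= min_dur, , drop = FALSE]
    if (nrow(runs) == 0L) return(NULL)
    event_list(type = type, threshold = thr, onset = runs$onset,
               duration = runs$duration, subject_id = subject_id)
  })
  do.call(bind_events, out)
}

merge_runs <- function(runs, merge_gap) {
  onset <- runs$onset
  end <- runs$onset + runs$duration
  grp <- cumsum(c(TRUE, onset[-1] - end[-length(end)] >= merge_gap))
  data.frame(
    onset = tapply(onset, grp, min),
    duration = tapply(end, grp, max) - tapply(onset, grp, min),
    row.names = NULL
  )
}

#' Derive a 1-Hz heart-rate channel from ECG
#'
#' R peaks are located with a derivative-energy detector: the squared first
#' difference of the ECG is smoothed over 25 ms, screened against a
#' block-adaptive threshold (a fraction of the rolling median of 2-s block
#' maxima), and surviving local maxima closer together than the refractory
#' period keep only the larger. Instantaneous heart rate 60/RR is assigned at
#' each R peak and resampled to 1 Hz by previous-value hold. Implausible RR
#' intervals (< 0.2 s or > 3 s) and segments without detectable QRS are
#' masked invalid.
#'
#' @param rec a [recording()] with an `ecg` channel, or a channel list.
#' @param channel ECG channel role when `rec` is a recording.
#' @param refractory minimum RR interval honoured by the peak picker, s.
#' @param rr_limits plausible RR range in seconds; rates outside are masked.
#' @param frac fraction of the local block-maximum energy used as detection
#'   threshold.
#' @return a heart-rate channel list (`values` in bpm, `rate` = 1 Hz,
#'   `valid`).
#' @export
compute_heart_rate <- function(rec, channel = "ecg", refractory = 0.2,
                               rr_limits = c(0.2, 3), frac = 0.25) {
  ch <- if (inherits(rec, "recording")) rec_channel(rec, channel) else rec
  rate <- ch$rate
  if (sum(ch$valid) / rate < 10) {
    stop("compute_heart_rate: fewer than 10 s of valid ECG", call. = FALSE)
  }
  x <- ch$values
  x[!ch$valid] <- 0
  e <- c(0, diff(x))^2
  w <- max(1L, round(0.025 * rate))
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0

  # block-adaptive threshold from 2-s block maxima
  blk <- max(1L, round(2 * rate))
  nb <- ceiling(length(e) / blk)
  bmax <- vapply(seq_len(nb), function(j) {
    i0 <- (j - 1L) * blk + 1L
    max(e[i0:min(j * blk, length(e))])
  }, numeric(1))
  k <- min(nb, 9L); if (k %% 2L == 0L) k <- k - 1L
  bref <- if (k >= 3L) stats::runmed(bmax, k, endrule = "median") else bmax
  bref <- pmax(bref, 0.05 * stats::median(bmax[bmax > 0]))
  thr <- rep(frac * bref, each = blk)[seq_along(e)]

  n <- length(e)
  core <- e[2:(n - 1L)]
  is_peak <- core > e[1:(n - 2L)] & core >= e[3:n] & core > thr[2:(n - 1L)]
  idx <- which(is_peak) + 1L
  if (length(idx) < 2L) {
    stop("compute_heart_rate: no detectable QRS complexes", call. = FALSE)
  }
  keep <- keep_spaced_peaks(idx, e[idx], round(refractory * rate))
  idx <- idx[keep]
  tpk <- (idx - 1L) / rate
  rr <- diff(tpk)
  ok <- rr >= rr_limits[1] & rr <= rr_limits[2]
  hr_inst <- 60 / rr

  # previous-value hold onto a 1-Hz grid
  dur <- floor(length(ch$values) / rate)
  tout <- seq_len(dur) - 1
  pos <- findInterval(tout, tpk[-1])     # last RR whose closing peak <= t
  values <- rep(NA_real_, dur)
  valid <- rep(FALSE, dur)
  has <- pos >= 1L
  values[has] <- hr_inst[pos[has]]
  valid[has] <- ok[pos[has]]
  # a sample inside an implausibly long (or absent) current RR interval has
  # no detectable QRS around it: mask the segment invalid
  last_peak <- tpk[pmin(pos + 1L, length(tpk))]
  contain_ok <- ifelse(pos + 1L <= length(ok), ok[pmax(pos + 1L, 1L)],
                       tout - last_peak <= rr_limits[2])
  valid <- valid & contain_ok
  list(values = values, rate = 1, valid = valid & !is.na(values))
}

#' Run all event detectors on a recording
#'
#' Convenience wrapper: detects breaths and pauses from the respiratory
#' channel, desaturations from SpO2, and bradycardia from the heart-rate
#' channel (derived from ECG via [compute_heart_rate()] when absent).
#'
#' @param rec a [recording()].
#' @param pause_bounds `c(short_min, short_max)` in seconds; long pauses are
#'   `> short_max`.
#' @param spo2_thresholds,desat_min_dur IH thresholds (%) and minimum
#'   duration (s).
#' @param brady_thresholds,brady_min_dur bradycardia thresholds (bpm) and
#'   minimum duration (s).
#' @param spo2_window if non-`NULL`, apply [smooth_spo2()] with this window
#'   before desaturation detection. Default `NULL`: monitor exports are
#'   already at the device averaging time.
#' @param ... passed to [detect_breaths()].
#' @return an `event_list` with all event types.
#' @export
detect_events <- function(rec, pause_bounds = c(3, 5),
                          spo2_thresholds = c(90, 88, 85), desat_min_dur = 5,
                          brady_thresholds = c(110, 100), brady_min_dur = 1,
                          spo2_window = NULL, ...) {
  sid <- rec$subject_id
  breaths <- detect_breaths(rec, ...)
  pauses <- detect_pauses(breaths, short_min = pause_bounds[1],
                          short_max = pause_bounds[2],
                          long_min = pause_bounds[2], subject_id = sid)
  spo2 <- rec_channel(rec, "spo2")
  if (!is.null(spo2_window)) spo2 <- smooth_spo2(spo2, window = spo2_window)
  desat <- detect_desaturations(spo2, thresholds = spo2_thresholds,
                                min_dur = desat_min_dur, subject_id = sid,
                                start_time = rec$start_time)
  hr <- if ("hr" %in% names(rec$channels)) {
    rec_channel(rec, "hr")
  } else {
    compute_heart_rate(rec)
  }
  brady <- detect_bradycardia(hr, thresholds = brady_thresholds,
                              min_dur = brady_min_dur, subject_id = sid,
                              start_time = rec$start_time)
  bind_events(pauses, desat, brady)
}
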