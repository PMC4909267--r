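test_that("breath detection recovers a known periodic signal", {
  rate <- 25
  tt <- seq(0, 60 - 1 / rate, by = 1 / rate)
  rec <- recording(list(resp = list(values = sin(2 * pi * tt), rate = rate)))
  br <- detect_breaths(rec)
  expect_gte(nrow(br), 59)
  expect_lte(nrow(br), 61)
  expect_true(all(abs(diff(br$onset) - 1) < 0.02))
})

test_that("a silent gap in breathing produces no onsets and one long pause", {
  rate <- 25
  tt <- seq(0, 120 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * tt)
  x[tt >= 60 & tt < 73] <- 0          # 13-s apneic silence
  rec <- recording(list(resp = list(values = x, rate = rate)))
  br <- detect_breaths(rec)
  expect_false(any(br$onset > 60.5 & br$onset < 72.5))
  ev <- detect_pauses(br)
  expect_equal(sum(ev$type == "pause_long"), 1)
  expect_equal(ev$duration[ev$type == "pause_long"], 13, tolerance = 0.1)
})

test_that("pause classification follows the silent-time definition", {
  # regular 1-s breathing: an extra d seconds of silence makes a pause of d
  gap_list <- function(d) {
    c(0:30, seq(31 + d, 60 + d))
  }
  expect_equal(nrow(detect_pauses(0:60)), 0)

  ev4 <- detect_pauses(gap_list(4))
  expect_equal(nrow(ev4), 1)
  expect_equal(ev4$type, "pause_short")
  expect_equal(ev4$duration, 4)
  expect_equal(ev4$onset, 31)         # last breath onset + median period

  ev13 <- detect_pauses(gap_list(13))
  expect_equal(ev13$type, "pause_long")
  expect_equal(ev13$duration, 13)

  # boundary convention: exactly 5 s is short, just above is long
  expect_equal(detect_pauses(gap_list(5))$type, "pause_short")
  expect_equal(detect_pauses(gap_list(5.01))$type, "pause_long")
  expect_equal(detect_pauses(gap_list(3))$type, character(0))

  # fewer than 2 breaths: empty
  expect_equal(nrow(detect_pauses(numeric(0))), 0)
  expect_equal(nrow(detect_pauses(5)), 0)
})

test_that("pause detector matches the first-principles oracle on random grids", {
  set.seed(401)
  for (rep in 1:25) {
    onsets <- cumsum(runif(80, 0.8, 1.3))
    ins <- sample(10:70, 3)
    for (i in ins) onsets[i:80] <- onsets[i:80] + runif(1, 0, 12)
    got <- detect_pauses(onsets)
    want <- oracle_pauses(onsets)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$duration, want$duration, tolerance = 1e-12)
      expect_equal(got$type, want$type)
      expect_equal(got$onset, want$onset, tolerance = 1e-12)
    }
  }
})

test_that("oximeter smoothing: constants pass through, steps ramp linearly", {
  cs <- smooth_spo2(rep(96, 100), window = 8, rate = 1)
  expect_equal(cs$values, rep(96, 100))

  # step 98 -> 88 at t0 = 20 s, 1 Hz: trailing 8-s mean ramps linearly and
  # first equals the new level one window after the last old sample
  x <- c(rep(98, 20), rep(88, 40))
  sm <- smooth_spo2(x, window = 8, rate = 1)
  t0 <- 20
  expect_equal(sm$values[t0 + 8 + 1], 88)                 # t = t0 + 8
  expect_lt(88, sm$values[t0 + 7])                        # not yet at t0+6
  ramp <- sm$values[(t0 + 1):(t0 + 8)]
  expect_equal(diff(ramp), rep(-10 / 8, 7), tolerance = 1e-12)

  # window of one sample period is the identity
  id <- smooth_spo2(c(97, 91, 95), window = 1, rate = 1)
  expect_equal(id$values, c(97, 91, 95))
})

test_that("oximeter smoothing averages valid samples only", {
  x <- c(rep(96, 10), rep(NA, 5), rep(96, 10))
  sm <- smooth_spo2(x, window = 4, rate = 1)
  expect_equal(sm$values[sm$valid], rep(96, sum(sm$valid)))
  # a window with no valid samples is invalid, not zero
  x2 <- c(rep(NA, 10), rep(90, 5))
  sm2 <- smooth_spo2(x2, window = 2, rate = 1)
  expect_false(any(sm2$valid[1:10]))
  expect_true(all(sm2$valid[11:15]))
})

test_that("desaturation detection applies thresholds and minimum duration", {
  base <- rep(96, 120)
  expect_equal(nrow(detect_desaturations(base, rate = 1)), 0)

  x <- base
  x[50:55] <- 89                       # 6 s at 89%
  ev <- detect_desaturations(x, rate = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$threshold, 90)
  expect_equal(ev$duration, 6)
  expect_equal(ev$onset, 49)

  x[50:53] <- 89; x[54:55] <- 96       # now only 4 s: below min duration
  expect_equal(nrow(detect_desaturations(x, rate = 1)), 0)

  # a sample equal to the threshold ends an episode (strict inequality)
  y <- base; y[30:40] <- 90
  expect_equal(nrow(detect_desaturations(y, rate = 1)), 0)
})

test_that("bradycardia detection counts runs at both thresholds", {
  expect_equal(nrow(detect_bradycardia(rep(150, 60), rate = 1)), 0)
  hr <- rep(150, 60); hr[20:29] <- 95  # 10 s at 95 bpm
  ev <- detect_bradycardia(hr, rate = 1)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$threshold, c(110, 100))
  expect_equal(ev$duration, c(10, 10))
  # a deep dip below 80 registers at both thresholds too
  hr2 <- rep(150, 60); hr2[10:14] <- 78
  expect_setequal(detect_bradycardia(hr2, rate = 1)$threshold, c(110, 100))
})

test_that("run detectors equal the brute-force scanner on random signals", {
  set.seed(402)
  for (rep in 1:40) {
    rate <- sample(c(1, 2, 5), 1)
    sig <- random_level_signal(sample(200:2000, 1), rate, base = 96,
                               dip_levels = c(92, 89, 87, 84))
    for (thr in c(90, 88, 85)) {
      got <- detect_desaturations(sig, thresholds = thr, min_dur = 5)
      want <- oracle_runs(sig$values, sig$valid, rate, thr, 5)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$onset, want$onset)
      expect_equal(got$duration, want$duration)
    }
  }
})

test_that("desaturation durations are monotone across nested thresholds", {
  set.seed(403)
  for (rep in 1:20) {
    sig <- random_level_signal(1500, 1, base = 96,
                               dip_levels = c(92, 89, 87, 84))
    ev <- detect_desaturations(sig, min_dur = 5)
    tot <- function(thr) sum(ev$duration[ev$threshold == thr])
    expect_lte(tot(85), tot(88))
    expect_lte(tot(88), tot(90))
  }
})

test_that("threshold lists are idempotent: single equals sublist of many", {
  set.seed(404)
  sig <- random_level_signal(3000, 1, base = 96,
                             dip_levels = c(92, 89, 87, 84))
  all3 <- detect_desaturations(sig, thresholds = c(90, 88, 85))
  only90 <- detect_desaturations(sig, thresholds = 90)
  sub <- all3[all3$threshold == 90, ]
  rownames(sub) <- NULL
  expect_equal(as.data.frame(sub), as.data.frame(only90))
})

test_that("event onsets are translation invariant", {
  set.seed(405)
  sig <- random_level_signal(1200, 1, base = 96, dip_levels = c(89, 84))
  ev0 <- detect_desaturations(sig, start_time = 0)
  ev9 <- detect_desaturations(sig, start_time = 900)
  expect_equal(nrow(ev0), nrow(ev9))
  expect_equal(ev9$onset, ev0$onset + 900)
  expect_equal(ev9$duration, ev0$duration)
})

test_that("heart rate derives from ECG impulse trains as 60/RR", {
  rate <- 250
  make_ecg <- function(beats, T) {
    x <- numeric(T * rate)
    i <- round(beats * rate) + 1L
    x[i] <- 1
    x
  }
  # constant RR = 0.4 s -> 150 bpm
  beats <- seq(0.2, 29.8, by = 0.4)
  hr <- compute_heart_rate(list(values = make_ecg(beats, 30), rate = rate,
                                valid = rep(TRUE, 30 * rate)))
  expect_equal(hr$rate, 1)
  expect_true(all(abs(hr$values[hr$valid] - 150) < 1))

  # alternating RR blocks: previous-value hold tracks 60/RR
  beats2 <- c(seq(0.2, 15, by = 0.4), seq(15.5, 30, by = 0.5))
  hr2 <- compute_heart_rate(list(values = make_ecg(beats2, 30), rate = rate,
                                 valid = rep(TRUE, 30 * rate)))
  expect_true(all(abs(hr2$values[5:12] - 150) < 1))
  expect_true(all(abs(hr2$values[20:28] - 120) < 1))
})

test_that("heart rate masks implausible RR and errors without valid ECG", {
  rate <- 250
  x <- numeric(40 * rate)
  beats <- c(seq(0.2, 15, by = 0.4), seq(25, 39.8, by = 0.4))  # 10-s dropout
  x[round(beats * rate) + 1L] <- 1
  hr <- compute_heart_rate(list(values = x, rate = rate,
                                valid = rep(TRUE, 40 * rate)))
  expect_false(any(hr$valid[18:24]))   # RR of 10 s is masked
  expect_error(
    compute_heart_rate(list(values = numeric(2500), rate = 250,
                            valid = rep(FALSE, 2500))),
    "valid ECG")
})
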