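test_that("schedules tile the study window", {
  s <- stim_schedule("off_first")
  expect_equal(nrow(s), 4)
  expect_equal(s$condition, c("OFF", "ON", "OFF", "ON"))
  expect_equal(s$end - s$start, rep(6 * 3600, 4))
  expect_equal(s$start[-1], s$end[-4])
  expect_equal(stim_schedule("on_first")$condition[1], "ON")
})

test_that("events take the condition of the block containing their onset", {
  s <- stim_schedule("off_first")
  ev <- event_list(type = "pause_long", onset = 5 * 3600, duration = 10)
  expect_equal(assign_events(ev, s)$condition, "OFF")

  # an event spanning a boundary belongs wholly to the earlier block
  ev2 <- event_list(type = "pause_long",
                    onset = 6 * 3600 - 2, duration = 10)
  expect_equal(assign_events(ev2, s)$condition, "OFF")
  ev3 <- event_list(type = "pause_long", onset = 6 * 3600, duration = 10)
  expect_equal(assign_events(ev3, s)$condition, "ON")

  bad <- event_list(type = "pause_long", onset = 25 * 3600, duration = 5)
  expect_error(assign_events(bad, s), "outside the schedule")
})

test_that("condition labels conserve counts and durations", {
  set.seed(501)
  s_off <- stim_schedule("off_first")
  s_on <- stim_schedule("on_first")
  for (i in 1:20) {
    n <- sample(5:80, 1)
    ev <- event_list(type = sample(c("pause_long", "desat", "brady"), n,
                                   replace = TRUE),
                     threshold = 90,
                     onset = runif(n, 0, 24 * 3600 - 60),
                     duration = runif(n, 1, 30))
    lab <- assign_events(ev, s_off)
    expect_equal(sum(lab$condition == "ON") + sum(lab$condition == "OFF"),
                 nrow(ev))
    # permuting block order relabels but never changes totals
    lab2 <- assign_events(ev, s_on)
    expect_equal(sum(lab$duration), sum(lab2$duration))
    expect_equal(table(lab$type), table(lab2$type))
    expect_equal(lab$condition,
                 ifelse(lab2$condition == "ON", "OFF", "ON"))
  }
})

test_that("subject summaries tally counts, durations and valid time", {
  s <- stim_schedule("off_first")
  empty <- summarize_subject(event_list(), s, subject_id = "S1")
  expect_equal(empty$pause_long_count_on, 0)
  expect_equal(empty$desat90_dur_off, 0)
  expect_equal(empty$valid_time_on, 12 * 3600)
  expect_equal(empty$valid_time_off, 12 * 3600)

  ev <- event_list(type = "pause_long",
                   onset = 6 * 3600 + c(100, 500, 900),
                   duration = c(6, 7, 10), subject_id = "S1")
  ev <- assign_events(ev, s)
  ss <- summarize_subject(ev, s)
  expect_equal(ss$pause_long_count_on, 3)
  expect_equal(ss$pause_long_dur_on, 23)
  expect_equal(ss$pause_long_count_off, 0)
  expect_equal(ss$order, "off_first")
})

test_that("valid time bookkeeping follows the mask", {
  rate <- 10
  n <- 2 * 3600 * rate
  valid <- rep(TRUE, n)
  valid[1:(1800 * rate)] <- FALSE       # first 30 min invalid, in OFF
  rec <- recording(list(resp = list(values = rnorm(n), rate = rate,
                                    valid = valid)))
  s <- stim_schedule("off_first", block_hours = 0.5, n_blocks = 4)
  ss <- summarize_subject(event_list(), s, rec)
  expect_equal(ss$valid_time_off, 1800)
  expect_equal(ss$valid_time_on, 3600)
})

test_that("summaries of a labeled synthetic recording match ground truth", {
  p <- noise_free_params(duration_h = 1, seed = 61, apnea_rate_off = 25)
  s <- short_schedule(1)
  g <- generate_recording(p, s)
  ev <- assign_events(detect_events(g$recording), s)
  ss <- summarize_subject(ev, s, g$recording)
  tp <- g$truth$pauses
  expect_equal(ss$pause_long_count_on + ss$pause_long_count_off,
               sum(tp$type == "pause_long"))
  expect_equal(ss$pause_long_count_on,
               sum(tp$type == "pause_long" & tp$condition == "ON"))
  expect_equal(ss$desat90_count_on + ss$desat90_count_off,
               sum(g$truth$desat$threshold == 90))
  expect_equal(ss$pause_long_dur_on + ss$pause_long_dur_off,
               sum(tp$duration[tp$type == "pause_long"]), tolerance = 0.05)
})
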