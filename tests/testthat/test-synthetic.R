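test_that("generation is bit-reproducible under a fixed seed", {
  p <- sim_params(duration_h = 0.25, seed = 77)
  s <- short_schedule(0.25)
  g1 <- generate_recording(p, s)
  g2 <- generate_recording(p, s)
  expect_identical(g1$recording$channels, g2$recording$channels)
  expect_identical(g1$truth$pauses, g2$truth$pauses)
})

test_that("a zero apnea rate yields a clean record", {
  p <- sim_params(duration_h = 0.5, apnea_rate_off = 0, seed = 5,
                  noise_sd = c(resp = 0, spo2 = 0, hr = 0))
  g <- generate_recording(p, short_schedule(0.5))
  expect_equal(nrow(g$truth$pauses), 0)
  expect_true(all(g$recording$channels$spo2$values >= p$baseline_spo2 - 1e-9))
  expect_true(all(g$recording$channels$hr$values >= p$baseline_hr - 1e-9))
})

test_that("infeasible apnea parameters are rejected", {
  p <- sim_params(duration_h = 1, apnea_rate_off = 200, seed = 1)
  expect_error(simulate_event_plan(p, short_schedule(1)), "infeasible")
})

test_that("ground-truth events lie inside the recording and cascade", {
  p <- noise_free_params(duration_h = 1, seed = 31, apnea_rate_off = 30)
  g <- generate_recording(p, short_schedule(1))
  T_s <- 3600
  tp <- g$truth$pauses
  expect_true(all(tp$onset > 0 & tp$onset + tp$duration < T_s))
  expect_true(all(g$truth$desat$onset + g$truth$desat$duration <= T_s))
  # every sufficiently long pause has an accompanying mild bradycardia:
  # depth 6 bpm/s crosses the 110-bpm threshold for pauses beyond ~8 s
  long_deep <- tp$onset[tp$duration > 9]
  b110 <- g$truth$brady[g$truth$brady$threshold == 110, ]
  for (t0 in long_deep) {
    expect_true(any(b110$onset > t0 & b110$onset < t0 + 30))
  }
})

test_that("noise-free detection recovers ground truth exactly", {
  p <- noise_free_params(duration_h = 2, seed = 13, apnea_rate_off = 30)
  g <- generate_recording(p, short_schedule(2))
  ev <- detect_events(g$recording)
  tp <- g$truth$pauses
  expect_equal(sum(ev$type == "pause_long"), sum(tp$type == "pause_long"))
  expect_equal(sum(ev$type == "pause_short"), sum(tp$type == "pause_short"))
  for (thr in c(90, 88, 85)) {
    expect_equal(sum(ev$type == "desat" & ev$threshold == thr),
                 sum(g$truth$desat$threshold == thr))
  }
  for (thr in c(110, 100)) {
    expect_equal(sum(ev$type == "brady" & ev$threshold == thr),
                 sum(g$truth$brady$threshold == thr))
  }
  got <- sort(ev$onset[ev$type == "pause_long"])
  want <- sort(tp$onset[tp$type == "pause_long"])
  expect_lt(max(abs(got - want)), 0.5)
})

test_that("the event plan honours the ON/OFF rate ratio", {
  p <- sim_params(duration_h = 24, apnea_rate_off = 20,
                  stim_rate_ratio = 0.6, seed = 1)
  s <- stim_schedule("off_first")
  n_on <- n_off <- 0
  set.seed(88)
  for (i in 1:40) {
    plan <- simulate_event_plan(p, s)
    n_on <- n_on + sum(plan$condition == "ON")
    n_off <- n_off + sum(plan$condition == "OFF")
  }
  expect_equal(n_on / n_off, 0.6, tolerance = 0.12)
})

test_that("count-mode cohorts are reproducible, ordered by coin flip, valid", {
  co1 <- generate_cohort(15, seed = 4, mode = "counts")
  co2 <- generate_cohort(15, seed = 4, mode = "counts")
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 15)
  expect_true(all(co1$order %in% c("on_first", "off_first")))
  expect_true(all(co1$pause_long_count_off >= 0))
  # the stimulation effect points the expected way on average
  expect_gt(mean(co1$pause_long_count_off), mean(co1$pause_long_count_on))
})

test_that("degenerate frailty and tiny cohorts are rejected", {
  expect_error(generate_cohort(15, sigma_u = 0), "random effect")
  expect_error(generate_cohort(1), "n_subjects")
})

test_that("a null cohort has no systematic condition effect", {
  set.seed(90)
  md <- replicate(60, {
    co <- generate_cohort(15, seed = sample.int(1e6, 1), mode = "counts",
                          rate_ratio = 1)
    mean(co$pause_long_count_off - co$pause_long_count_on)
  })
  expect_lt(abs(mean(md)) / (sd(md) / sqrt(length(md))), 4)
})
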