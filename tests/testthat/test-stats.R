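test_that("transforms have their closed forms and reject negatives", {
  expect_equal(transform_counts(0, "lnp1"), 0)
  expect_equal(transform_counts(exp(1) - 1, "lnp1"), 1)
  expect_equal(transform_counts(99, "log10p1"), 2)
  expect_equal(transform_counts(c(4, 9), "sqrt"), c(2, 3))
  expect_error(transform_counts(-1, "lnp1"), "negative")
})

test_that("paired_test matches hand-computed oracles", {
  # identical conditions: exact null result
  r0 <- paired_test(c(3, 5, 8), c(3, 5, 8))
  expect_equal(r0$t, 0)
  expect_equal(r0$md, 0)
  expect_equal(r0$pct_change, 0)

  # 3-pair worked example against the closed-form t on transformed diffs
  off <- c(10, 12, 14); on <- c(8, 9, 10)
  r <- paired_test(off, on, transform = "lnp1")
  d <- log1p(off) - log1p(on)
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(r$t, t_oracle, tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$md, mean(off) - mean(on))
  expect_equal(r$p, 2 * pt(-abs(t_oracle), 2), tolerance = 1e-10)

  # identity transform equals a textbook paired t from first principles
  set.seed(601)
  for (i in 1:10) {
    a <- rpois(12, 50); b <- rpois(12, 40)
    r2 <- paired_test(a, b, transform = "identity")
    dd <- a - b
    expect_equal(r2$t, mean(dd) / (sd(dd) / sqrt(12)), tolerance = 1e-10)
    expect_equal(r2$p, 2 * pt(-abs(r2$t), 11), tolerance = 1e-10)
  }
})

test_that("t is scale invariant and MD keeps the OFF-minus-ON convention", {
  set.seed(602)
  a <- rpois(15, 40); b <- rpois(15, 30)
  r1 <- paired_test(a, b, "identity")
  r2 <- paired_test(3 * a, 3 * b, "identity")
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
  expect_equal(r2$md, 3 * r1$md, tolerance = 1e-10)
  expect_gt(r1$md, 0)        # fewer events under ON -> positive MD
  expect_equal(sign(r1$pct_change), sign(r1$md))
})

test_that("degenerate paired input is flagged, not crashed", {
  r <- paired_test(c(5, 5, 5), c(5, 5, 5))
  expect_true(r$degenerate)
  expect_equal(r$t, 0)
  r2 <- paired_test(c(5, 6, 7), c(4, 5, 6), transform = "identity")
  expect_true(r2$degenerate)      # constant non-zero differences
  expect_true(is.na(r2$t))
})

test_that("normality screen reports both tests and flags edge cases", {
  set.seed(603)
  x <- rnorm(50)
  ns <- normality_screen(x)
  expect_true(ns$ks_p > 0.01)
  expect_true(ns$shapiro_p > 0.001)
  expect_error(normality_screen(c(1, 2)), "at least 3")
  const <- normality_screen(rep(2, 10))
  expect_true(is.na(const$shapiro_p))
  expect_match(const$note, "constant")
})

test_that("log transform improves normality of skewed paired counts", {
  set.seed(604)
  raw_p <- tr_p <- numeric(80)
  for (i in 1:80) {
    u <- exp(rnorm(15, 0, 0.6))
    off <- rpois(15, 200 * u)
    on <- rpois(15, 120 * u)
    raw_p[i] <- normality_screen(off - on)$shapiro_p
    tr_p[i] <- normality_screen(log1p(off) - log1p(on))$shapiro_p
  }
  expect_gt(median(tr_p), median(raw_p))
})

test_that("percent change uses the reduction-is-negative sign convention", {
  co <- generate_cohort(5, seed = 3, mode = "counts")
  co$pause_long_count_off[1] <- 100
  co$pause_long_count_on[1] <- 61
  co$desat85_count_off[2] <- 0
  pc <- percent_change_table(co)
  expect_equal(pc$pause_long_count_pct[1], -39)
  expect_true(is.na(pc$desat85_count_pct[2]))
})

test_that("cohort_report covers all outcomes and names missing columns", {
  co <- generate_cohort(12, seed = 9, mode = "counts")
  rep <- cohort_report(co)
  expect_equal(nrow(rep), 14)
  expect_setequal(rep$measure, c("count", "dur"))
  expect_true(all(rep$df == 11))
  expect_match(attr(rep, "note"), "uncorrected")

  co$brady100_dur_off <- NULL
  expect_error(cohort_report(co), "brady100_dur_off")
})
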