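#' Normalizing transforms for count and duration outcomes
#'
#' Elementwise `sqrt(x)`, `log10(x + 1)` or `ln(x + 1)`. Event counts and
#' total durations are right-skewed; the paired analysis is run on a
#' transformed scale and raw-scale means are reported for interpretation.
#' `"identity"` is accepted for cross-checking against a textbook paired t.
#'
#' @param x non-negative numeric vector.
#' @param kind one of `"lnp1"`, `"log10p1"`, `"sqrt"`, `"identity"`.
#' @return transformed vector.
#' @export
transform_counts <- function(x, kind = c("lnp1", "log10p1", "sqrt",
                                         "identity")) {
  kind <- match.arg(kind)
  if (any(x < 0, na.rm = TRUE)) {
    stop("transform_counts: negative input", call. = FALSE)
  }
  switch(kind,
         lnp1 = log1p(x),
         log10p1 = log10(x + 1),
         sqrt = sqrt(x),
         identity = x)
}

#' Normality screen of paired differences
#'
#' Applies a Kolmogorov-Smirnov-type test (Lilliefors-corrected for
#' estimated mean and SD when n >= 5, plain KS with estimated parameters
#' below that) and the Shapiro-Wilk test to a vector of paired differences.
#' Results are reported, never auto-enforced: transform choice stays with
#' the analyst.
#'
#' @param diffs numeric vector of (possibly transformed) paired
#'   differences, n >= 3.
#' @return data frame with `ks_stat`, `ks_p`, `shapiro_stat`, `shapiro_p`
#'   and a `note` (non-empty when a test is undefined, e.g. constant
#'   input).
#' @export
normality_screen <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3) stop("normality_screen: need at least 3 values", call. = FALSE)
  note <- ""
  if (stats::sd(diffs) == 0) {
    return(data.frame(ks_stat = NA_real_, ks_p = NA_real_,
                      shapiro_stat = NA_real_, shapiro_p = NA_real_,
                      note = "constant differences: normality undefined",
                      stringsAsFactors = FALSE))
  }
  if (n >= 5) {
    ks <- nortest::lillie.test(diffs)
  } else {
    ks <- stats::ks.test(diffs, "pnorm", mean(diffs), stats::sd(diffs))
    note <- "n < 5: plain KS with estimated parameters (approximate)"
  }
  sw <- stats::shapiro.test(diffs)
  data.frame(ks_stat = unname(ks$statistic), ks_p = ks$p.value,
             shapiro_stat = unname(sw$statistic), shapiro_p = sw$p.value,
             note = note, stringsAsFactors = FALSE)
}

#' Paired comparison of one outcome between conditions
#'
#' The within-subject comparison of the crossover: the t statistic, degrees
#' of freedom and (two-sided) p value come from a paired t-test on
#' transformed values (default ln(x+1)); the mean difference (MD), condition
#' means with standard errors, and percent change are computed on the raw
#' scale for interpretation. The MD sign convention is OFF - ON, so a
#' positive MD is a reduction under stimulation; percent change is
#' 100 * MD / OFF mean.
#'
#' @param off,on equal-length paired vectors (no-stimulation and
#'   stimulation values per subject), n >= 2.
#' @param transform transform applied before the t-test; see
#'   [transform_counts()].
#' @param outcome outcome name carried into the result.
#' @return an object of class `paired_test_result`: a one-row data frame
#'   with `outcome`, `n`, `mean_off`, `se_off`, `mean_on`, `se_on`, `md`,
#'   `pct_change`, `t`, `df`, `p`, `transform`, `degenerate`.
#' @export
paired_test <- function(off, on, transform = "lnp1", outcome = "outcome") {
  stopifnot(length(off) == length(on), length(off) >= 2)
  keep <- is.finite(off) & is.finite(on)
  off <- off[keep]; on <- on[keep]
  n <- length(off)
  toff <- transform_counts(off, transform)
  ton <- transform_counts(on, transform)
  d <- toff - ton
  se <- function(x) stats::sd(x) / sqrt(length(x))
  md <- mean(off) - mean(on)
  pct <- if (mean(off) != 0) 100 * md / mean(off) else NA_real_
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    tval <- if (all(d == 0)) 0 else NA_real_
    pval <- if (all(d == 0)) 1 else NA_real_
  } else {
    tt <- stats::t.test(toff, ton, paired = TRUE)
    tval <- unname(tt$statistic)
    pval <- tt$p.value
  }
  out <- data.frame(outcome = outcome, n = n,
                    mean_off = mean(off), se_off = se(off),
                    mean_on = mean(on), se_on = se(on),
                    md = md, pct_change = pct,
                    t = tval, df = n - 1L, p = pval,
                    transform = transform, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_test_result", "data.frame")
  out
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "%s: OFF %.1f +/- %.1f, ON %.1f +/- %.1f, MD = %.1f (%.0f%%), t(%d) = %.3f, p = %.4g [%s]\n",
    x$outcome, x$mean_off, x$se_off, x$mean_on, x$se_on, x$md,
    x$pct_change, x$df, x$t, x$p, x$transform))
  invisible(x)
}

cohort_measure <- function(cohort, outcome, measure, cond) {
  cohort[[paste0(outcome, "_", measure, "_", cond)]]
}

#' Full paired analysis of a cohort table
#'
#' Runs [paired_test()] for every outcome's count and total duration (7
#' outcomes x 2 measures), each OFF vs ON, on the chosen transform, and
#' flags significance at `alpha`. No multiple-testing correction is applied
#' (the analysis reports one uncorrected paired t per outcome); a note to
#' that effect is attached to the result.
#'
#' @param cohort a `cohort_table` (see [generate_cohort()] /
#'   [read_cohort_table()]).
#' @param transform transform for the t-tests (default `"lnp1"`).
#' @param alpha significance level.
#' @return a `cohort_report` data frame: one row per outcome x measure with
#'   the [paired_test()] columns plus `measure`, `significant`, and the
#'   normality screen of the transformed differences.
#' @export
cohort_report <- function(cohort, transform = "lnp1", alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  rows <- list()
  for (oc in outcome_levels()) {
    for (ms in c("count", "dur")) {
      off <- cohort_measure(cohort, oc, ms, "off")
      on <- cohort_measure(cohort, oc, ms, "on")
      r <- paired_test(off, on, transform = transform,
                       outcome = paste0(oc, "_", ms))
      r$measure <- ms
      r$significant <- !is.na(r$p) & r$p < alpha
      ns <- if (r$n >= 3) {
        normality_screen(transform_counts(off, transform) -
                           transform_counts(on, transform))
      } else {
        data.frame(ks_stat = NA_real_, ks_p = NA_real_,
                   shapiro_stat = NA_real_, shapiro_p = NA_real_,
                   note = "n < 3", stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- cbind(r, ns)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "note") <-
    "p values are two-sided and uncorrected for multiple comparisons"
  class(out) <- c("cohort_report", "data.frame")
  out
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("Paired crossover analysis (", x$transform[1], " transform), n = ",
      x$n[1], " subjects\n", sep = "")
  df <- data.frame(outcome = x$outcome,
                   mean_off = round(x$mean_off, 1),
                   mean_on = round(x$mean_on, 1),
                   MD = round(x$md, 1),
                   pct = round(x$pct_change, 0),
                   t = round(x$t, digits),
                   p = signif(x$p, 3),
                   sig = ifelse(x$significant, "*", ""))
  print.data.frame(df, row.names = FALSE)
  cat("Note:", attr(x, "note"), "\n")
  invisible(x)
}

#' Per-subject percent change for every outcome
#'
#' Percent change under stimulation, per subject and outcome:
#' `100 * (ON - OFF) / OFF`. A negative value indicates a reduction in
#' response to stimulation. Subjects with OFF = 0 get `NA` (undefined, not
#' infinite).
#'
#' @param cohort a `cohort_table`.
#' @return data frame: `subject_id` plus one `<outcome>_<measure>_pct`
#'   column per outcome and measure.
#' @export
percent_change_table <- function(cohort) {
  cohort <- validate_cohort(cohort)
  out <- data.frame(subject_id = cohort$subject_id,
                    stringsAsFactors = FALSE)
  for (oc in outcome_levels()) {
    for (ms in c("count", "dur")) {
      off <- cohort_measure(cohort, oc, ms, "off")
      on <- cohort_measure(cohort, oc, ms, "on")
      out[[paste0(oc, "_", ms, "_pct")]] <-
        ifelse(off > 0, 100 * (on - off) / off, NA_real_)
    }
  }
  out
}
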