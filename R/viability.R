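#' Wilson score confidence interval for a binomial proportion
#'
#' The 95% (by default) binomial confidence interval used for viability
#' error bars. The Wilson score interval inverts the normal approximation to
#' the score test, behaves well at small n and at proportions near 0 or 1,
#' and always lies inside [0, 1].
#'
#' @param successes Number of successes (vectorised).
#' @param n Number of trials; must be >= 1.
#' @param level Confidence level, default 0.95.
#' @return Tibble: successes, n, estimate, conf_low, conf_high, level.
#' @examples
#' binomial_ci(5, 10)
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  if (any(n < 1)) abort("`n` must be >= 1.", class = "defsup_input_error")
  if (any(successes < 0 | successes > n)) {
    abort("`successes` must lie in [0, n].", class = "defsup_input_error")
  }
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).",
                                      class = "defsup_input_error")
  p <- successes / n
  z <- qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp away floating-point noise at the p = 0 / p = 1 boundaries
  tibble(
    successes = successes, n = n, estimate = p,
    conf_low = pmin(pmax(0, centre - half), p),
    conf_high = pmax(pmin(1, centre + half), p),
    level = level
  )
}

#' Control-normalized mutant viability
#'
#' Viability of a mutant genotype from a balancer cross, normalized to a
#' parallel control cross: the ratio of mutant to balancer males in the test
#' cross divided by the same ratio for the control chromosome, cancelling the
#' balancer's own viability cost. The confidence interval is computed on the
#' test-cross mutant proportion `test_mut / (test_mut + test_bal)` (the
#' ratio-of-ratios has no standard interval).
#'
#' @param test_mut,test_bal Mutant and balancer male counts in the test cross.
#' @param ctrl_mut,ctrl_bal Counts from the parallel control cross.
#' @param level Confidence level for the binomial interval.
#' @return Tibble: viability, ci_low, ci_high, n (total test-cross males).
#' @examples
#' normalized_viability(50, 100, 100, 100)
#' @export
normalized_viability <- function(test_mut, test_bal, ctrl_mut, ctrl_bal,
                                 level = 0.95) {
  if (any(c(test_mut, test_bal, ctrl_mut, ctrl_bal) < 0)) {
    abort("Counts must be nonnegative.", class = "defsup_input_error")
  }
  if (test_bal == 0 || ctrl_bal == 0 || ctrl_mut == 0) {
    abort("Viability undefined: zero balancer or control-mutant count.",
          class = "defsup_undefined_viability")
  }
  ci <- binomial_ci(test_mut, test_mut + test_bal, level)
  tibble(
    viability = (test_mut / test_bal) / (ctrl_mut / ctrl_bal),
    ci_low = ci$conf_low,
    ci_high = ci$conf_high,
    n = test_mut + test_bal
  )
}

#' Test of equal or given proportions for two crosses
#'
#' Compares two binomial proportions (e.g. viability of two genotypes) by the
#' Pearson chi-square test on the 2x2 table, with Yates continuity correction
#' by default; two-sided p from chi-square with 1 df. This is
#' [stats::prop.test()]'s test, exposed with a tabular result.
#'
#' @param x1,n1 Successes and trials in the first group.
#' @param x2,n2 Successes and trials in the second group.
#' @param correct Apply Yates continuity correction (clipped at zero).
#' @return Tibble: statistic, p_value, estimate1, estimate2, correct.
#' @examples
#' test_equal_proportions(30, 100, 10, 100)
#' @export
test_equal_proportions <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 < 1 || n2 < 1) abort("Both `n` must be >= 1.", class = "defsup_input_error")
  if ((x1 + x2 == 0) || (x1 + x2 == n1 + n2)) {
    abort("Test undefined: a margin of the 2x2 table is zero.",
          class = "defsup_undefined_test")
  }
  ht <- suppressWarnings(
    prop.test(c(x1, x2), c(n1, n2), correct = correct)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    estimate1 = x1 / n1,
    estimate2 = x2 / n2,
    correct = correct
  )
}

#' Two-sample Student's t-test with a zero-variance guard
#'
#' Replicate-mean comparisons: unpaired or paired, one- or two-sided. When
#' every observation is identical (or all paired differences are zero) the
#' t statistic is undefined; the comparison is then reported as p = 1 with
#' `zero_variance = TRUE`, i.e. no evidence of a difference.
#'
#' @param a,b Numeric replicate vectors (paired requires equal lengths).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param paired Paired test?
#' @return Tibble: statistic, p_value, mean_a, mean_b, alternative, paired,
#'   zero_variance.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(a, b, alternative = "two.sided", paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs >= 2 replicates.", class = "defsup_input_error")
  }
  if (paired && length(a) != length(b)) {
    abort("Paired test requires equal group lengths.", class = "defsup_input_error")
  }
  degenerate <- if (paired) sd(a - b) == 0 else sd(a) == 0 && sd(b) == 0
  if (degenerate) {
    delta <- mean(a) - mean(b)
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- switch(alternative,
                two.sided = as.numeric(delta == 0),
                less = if (delta < 0) 0 else 1,
                greater = if (delta > 0) 0 else 1)
    return(tibble(statistic = stat, p_value = p, mean_a = mean(a),
                  mean_b = mean(b), alternative = alternative, paired = paired,
                  zero_variance = TRUE))
  }
  ht <- t.test(a, b, alternative = alternative, paired = paired)
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    mean_a = mean(a), mean_b = mean(b),
    alternative = alternative, paired = paired, zero_variance = FALSE
  )
}

#' Twice the standard error of the mean
#'
#' The +/- 2 SEM error-bar half-width used for replicate means, a close
#' approximation of the 95% confidence interval.
#'
#' @param values Numeric vector with >= 2 replicates.
#' @return The half-width `2 * sd(values) / sqrt(length(values))`.
#' @examples
#' sem2(c(1, 2, 3))
#' @export
sem2 <- function(values) {
  if (length(values) < 2) abort("Need >= 2 replicates.", class = "defsup_input_error")
  2 * sd(values) / sqrt(length(values))
}
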