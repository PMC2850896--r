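# Method-comparison statistics: paired tests with a normality gate,
# identity regression, Bland-Altman agreement, moment-based LOA
# reconstruction, correlation power, and covariate correlations.
#
# Sign conventions: method differences are DXA minus 4C; regressions put
# the criterion (4C) on the left-hand side and the predictor (DXA) on the
# right.

#' Paired comparison with a normality gate
#'
#' Compares two paired samples with a paired t-test when the differences
#' pass a Shapiro-Wilk normality check, and a Wilcoxon signed-rank test
#' otherwise. The branch taken is reported (and worth logging: the gate is
#' a modelling decision, not a fact about the data).
#'
#' @param x,y paired numeric vectors (length >= 3).
#' @param normality_alpha Shapiro-Wilk significance level for the gate.
#' @return List: `statistic`, `p_value`, `test` ("paired t-test" or
#'   "wilcoxon signed-rank"), `normality_p`, `mean_diff`.
#' @export
paired_comparison <- function(x, y, normality_alpha = 0.05) {
  .check_num(x, "x"); .check_num(y, "y")
  if (length(x) != length(y)) .stop("`x` and `y` must have equal length")
  if (length(x) < 3) .stop("need at least 3 pairs")
  d <- x - y
  if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (all(abs(d) < 1e-12))
      return(list(statistic = 0, p_value = 1, test = "paired t-test",
                  normality_p = NA_real_, mean_diff = 0))
    .stop("paired differences have zero variance but non-zero mean: degenerate input")
  }
  # shapiro.test is defined for 3..5000 observations; above that, gate on a
  # deterministic evenly-spaced subsample
  d_gate <- if (length(d) > 5000) d[round(seq(1, length(d), length.out = 5000))] else d
  norm_p <- stats::shapiro.test(d_gate)$p.value
  if (norm_p >= normality_alpha) {
    ht <- stats::t.test(x, y, paired = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "paired t-test", normality_p = norm_p, mean_diff = mean(d))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "wilcoxon signed-rank", normality_p = norm_p, mean_diff = mean(d))
  }
}

#' One-sample t-test against a reference constant
#'
#' Used to compare group means (e.g. FFM hydration, mineral and protein
#' fractions) with reference-population values.
#'
#' @param x numeric vector, n >= 3, non-zero variance.
#' @param ref reference constant.
#' @return List with `t`, `p_value`, `mean`, `ref`.
#' @export
one_sample_vs_reference <- function(x, ref) {
  .check_num(x, "x"); .check_num(ref, "ref")
  if (length(x) < 3) .stop("need at least 3 observations")
  if (sd(x) == 0) .stop("`x` has zero variance")
  ht <- stats::t.test(x, mu = ref)
  list(t = unname(ht$statistic), p_value = ht$p.value, mean = mean(x), ref = ref)
}

#' Regression of the criterion on the predictor, tested against identity
#'
#' Ordinary least squares of the criterion method (4C) on the predictor
#' (DXA), with the standard error of estimation `SEE = sqrt(SSE / (n - 2))`
#' and t-tests of the slope against 1 and the intercept against 0 (the line
#' of identity).
#'
#' @param criterion criterion-method values (4C).
#' @param predictor predictor-method values (DXA).
#' @return List: `slope`, `intercept`, `r`, `see`, `slope_p_vs_1`,
#'   `intercept_p_vs_0`, `n`.
#' @export
identity_regression <- function(criterion, predictor) {
  .check_num(criterion, "criterion"); .check_num(predictor, "predictor")
  if (length(criterion) != length(predictor)) .stop("input lengths differ")
  n <- length(criterion)
  if (n < 3) .stop("need at least 3 observations")
  if (sd(predictor) == 0) .stop("predictor has zero variance")
  fit <- stats::lm(criterion ~ predictor)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning handled below
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  se <- sm$coefficients[, "Std. Error"]
  df <- n - 2
  # exact fits have (numerically) zero residual SE: a coefficient then either
  # equals its identity value (p = 1) or differs with certainty (p below the
  # numeric floor)
  exact <- sm$sigma < 1e-10 * max(1, max(abs(criterion)))
  p2 <- function(delta, se1) {
    if (exact) return(if (abs(delta) < 1e-8) 1 else 0)
    2 * stats::pt(-abs(delta / se1), df)
  }
  list(slope = slope, intercept = intercept,
       r = sign(slope) * sqrt(sm$r.squared), see = sm$sigma,
       slope_p_vs_1 = p2(slope - 1, se[2]),
       intercept_p_vs_0 = p2(intercept, se[1]),
       n = n)
}

#' Percent of criterion variance explained
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @return `100 * r^2`, rounded to the nearest integer (reporting scale).
#' @export
r_squared_percent <- function(r) {
  .check_num(r, "r")
  if (any(abs(r) > 1)) .stop("`r` must lie in [-1, 1]")
  round(100 * r^2)
}

#' Bland-Altman agreement between two methods
#'
#' Differences are `method_a - method_b`; by package convention `method_a`
#' is DXA and `method_b` the 4C criterion. Bias is the mean difference and
#' the 95% limits of agreement are `bias +/- multiplier * SD(diff)` (sample
#' SD). The trend is the Pearson correlation between the differences and
#' the per-subject mean of the two methods (proportional bias).
#'
#' @param method_a,method_b paired numeric vectors (length >= 3).
#' @param multiplier LOA multiplier (default 1.96, the 95% definition).
#' @return List: `n`, `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `trend_r`, `trend_p`, `trend_computable`.
#' @export
bland_altman <- function(method_a, method_b, multiplier = 1.96) {
  .check_num(method_a, "method_a"); .check_num(method_b, "method_b")
  if (length(method_a) != length(method_b)) .stop("input lengths differ")
  n <- length(method_a)
  if (n < 3) .stop("need at least 3 pairs")
  d <- method_a - method_b
  m <- (method_a + method_b) / 2
  s <- sd(d)
  if (s == 0)
    warning("zero difference variance: limits of agreement collapse to the bias",
            call. = FALSE)
  trend_ok <- s > 0 && sd(m) > 0
  trend <- if (trend_ok) stats::cor.test(d, m) else NULL
  list(n = n, bias = mean(d), sd_diff = s,
       loa_lower = mean(d) - multiplier * s,
       loa_upper = mean(d) + multiplier * s,
       trend_r = if (trend_ok) unname(trend$estimate) else NA_real_,
       trend_p = if (trend_ok) trend$p.value else NA_real_,
       trend_computable = trend_ok)
}

#' Limits of agreement reconstructed from summary moments
#'
#' Closed-form Bland-Altman reconstruction when only the two methods'
#' means, SDs and their correlation are available:
#' `SD(diff) = sqrt(sd_a^2 + sd_b^2 - 2 r sd_a sd_b)`,
#' `LOA = (mean_a - mean_b) +/- multiplier * SD(diff)`. Fed the sample
#' moments of paired data it agrees exactly with [bland_altman()].
#'
#' @param mean_a,sd_a moments of method a (DXA).
#' @param mean_b,sd_b moments of method b (4C).
#' @param r_ab correlation between the methods.
#' @param multiplier LOA multiplier.
#' @return List: `bias`, `sd_diff`, `loa_lower`, `loa_upper`.
#' @export
moment_loa <- function(mean_a, sd_a, mean_b, sd_b, r_ab, multiplier = 1.96) {
  .check_num(sd_a, "sd_a", positive = TRUE)
  .check_num(sd_b, "sd_b", positive = TRUE)
  .check_num(r_ab, "r_ab")
  if (abs(r_ab) > 1) .stop("|r_ab| must be <= 1")
  bias <- mean_a - mean_b
  s <- sqrt(sd_a^2 + sd_b^2 - 2 * r_ab * sd_a * sd_b)
  list(bias = bias, sd_diff = s,
       loa_lower = bias - multiplier * s, loa_upper = bias + multiplier * s)
}

#' Smallest correlation detectable at given power
#'
#' Fisher-z power solution for a two-sided test of zero correlation:
#' solves `atanh(r) * sqrt(n - 3) = z_{1-alpha/2} + z_{power}`.
#'
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return The minimal detectable `|r|`.
#' @examples
#' detectable_correlation(27, 0.05, 0.80)
#' @export
detectable_correlation <- function(n, alpha = 0.05, power = 0.80) {
  if (!is.numeric(n) || n < 4) .stop("`n` must be >= 4")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    .stop("`alpha` and `power` must lie in (0, 1)")
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}

#' Correlation between method differences and a covariate
#'
#' Pearson correlation with two-sided p-value, used for scanning whether
#' the DXA-minus-4C differences relate to weight change, FFM-density
#' change, FFM-fraction changes or regional tissue changes. Zero variance
#' in either input yields a not-computable result instead of an error.
#'
#' @param diffs per-subject method differences.
#' @param covariate candidate explanatory variable, same length.
#' @return List: `r`, `p_value`, `n`, `computable`.
#' @export
correlate_differences <- function(diffs, covariate) {
  .check_num(diffs, "diffs"); .check_num(covariate, "covariate")
  if (length(diffs) != length(covariate)) .stop("input lengths differ")
  if (length(diffs) < 3) .stop("need at least 3 observations")
  if (sd(diffs) == 0 || sd(covariate) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(diffs),
                computable = FALSE))
  ct <- stats::cor.test(diffs, covariate)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(diffs),
       computable = TRUE)
}

#' Full agreement report for one variable pair
#'
#' Bundles the group-level and individual-level comparison of one variable
#' measured by DXA and the 4C criterion: paired mean comparison (with
#' normality gate), identity regression of 4C on DXA, and Bland-Altman
#' bias, limits of agreement and trend.
#'
#' @param criterion 4C values.
#' @param predictor DXA values.
#' @param variable label used in printing.
#' @param multiplier LOA multiplier.
#' @param normality_alpha gate level for the paired test.
#' @return Object of class `agreement_report` (a list).
#' @export
agreement_report <- function(criterion, predictor, variable = "variable",
                             multiplier = 1.96, normality_alpha = 0.05) {
  reg <- identity_regression(criterion, predictor)
  ba <- bland_altman(predictor, criterion, multiplier)  # DXA minus 4C
  cmp <- paired_comparison(predictor, criterion, normality_alpha)
  structure(c(list(variable = variable), reg, ba,
              list(mean_comparison_p = cmp$p_value,
                   mean_comparison_test = cmp$test,
                   r2_percent = r_squared_percent(reg$r))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report: %s (n = %d)\n", x$variable, x$n))
  cat(sprintf("  regression 4C ~ DXA: slope %.2f  intercept %.2f  r %.2f  SEE %.2f\n",
              x$slope, x$intercept, x$r, x$see))
  cat(sprintf("    slope vs 1: p = %.3f   intercept vs 0: p = %.3f\n",
              x$slope_p_vs_1, x$intercept_p_vs_0))
  cat(sprintf("  bias (DXA - 4C) %.2f   95%% LOA [%.2f, %.2f]\n",
              x$bias, x$loa_lower, x$loa_upper))
  if (x$trend_computable)
    cat(sprintf("  trend (diff vs mean): r = %.2f, p = %.4f\n", x$trend_r, x$trend_p))
  else cat("  trend: not computable\n")
  cat(sprintf("  mean comparison: p = %.4f (%s)\n",
              x$mean_comparison_p, x$mean_comparison_test))
  invisible(x)
}
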