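#' @name evaluation
#' @title Scoring-function evaluation statistics
#'
#' @description
#' Predictions are scored the way scoring-function benchmarks report them:
#' Pearson and Spearman correlations between observed and predicted
#' pAffinity, and the standard deviation of the observations about the
#' least-squares regression line on the predictions (with n - 2 in the
#' denominator), which absorbs any affine miscalibration.  Two fitted
#' methods are compared by the Fisher r-to-z test on their correlations
#' and by an F-test on their residual standard deviations, at the
#' conventional 0.05 threshold.
NULL

.check_xy <- function(x, y, min_n = 3L) {
  if (length(x) != length(y))
    stop_bindsig("x and y have different lengths", class = "bindsig_stat_error")
  if (length(x) < min_n)
    stop_bindsig("need at least %d observations", min_n,
                 class = "bindsig_stat_error")
  if (anyNA(x) || anyNA(y))
    stop_bindsig("NA values in input", class = "bindsig_stat_error")
}

#' Pearson product-moment correlation
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  .check_xy(x, y)
  if (sd(x) == 0 || sd(y) == 0)
    stop_bindsig("constant input has no defined correlation",
                 class = "bindsig_stat_error")
  cor(x, y, method = "pearson")
}

#' Spearman rank correlation (average ranks for ties)
#' @inheritParams pearson_r
#' @return rank correlation coefficient in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  .check_xy(x, y)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_bindsig("constant ranks have no defined correlation",
                 class = "bindsig_stat_error")
  cor(x, y, method = "spearman")
}

#' Residual standard deviation about the regression line
#'
#' The benchmark convention: observed values are regressed on predicted
#' values by least squares and the standard deviation of the residuals is
#' reported with an n - 2 denominator.  \code{method = "raw"} instead
#' returns the standard deviation of the paired differences.
#'
#' @param pred predicted values.
#' @param obs observed values.
#' @param method \code{"regression"} (default) or \code{"raw"}.
#' @return non-negative residual standard deviation, in pK units.
#' @export
residual_sd <- function(pred, obs, method = c("regression", "raw")) {
  method <- match.arg(method)
  .check_xy(pred, obs)
  if (method == "raw") return(sd(obs - pred))
  if (sd(pred) == 0)
    stop_bindsig("constant predictions cannot be regressed on",
                 class = "bindsig_stat_error")
  fit <- lm(obs ~ pred)
  sqrt(sum(stats::residuals(fit)^2) / (length(obs) - 2L))
}

#' Fisher r-to-z test for two independent correlations
#'
#' \code{z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))}, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, both >= 4.
#' @return list with \code{z} and \code{p} (two-sided).
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_bindsig("|r| = 1 has an infinite z-transform",
                 class = "bindsig_stat_error")
  if (n1 < 4L || n2 < 4L)
    stop_bindsig("need n >= 4 on both sides", class = "bindsig_stat_error")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' F-test for two residual standard deviations
#'
#' \code{F = (max(sd1, sd2) / min(sd1, sd2))^2} on residual degrees of
#' freedom (n - 2 on each side, matching the regression-residual SD).
#' One-sided by default.
#'
#' @param sd1,sd2 positive residual standard deviations.
#' @param n1,n2 sample sizes, both >= 4.
#' @param alternative \code{"one.sided"} (default) or \code{"two.sided"}.
#' @return list with \code{f} (the variance ratio, >= 1 by construction),
#'   \code{df1}, \code{df2} and \code{p}.
#' @export
f_test_sd <- function(sd1, n1, sd2, n2,
                      alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  if (sd1 <= 0 || sd2 <= 0)
    stop_bindsig("standard deviations must be positive",
                 class = "bindsig_stat_error")
  if (n1 < 4L || n2 < 4L)
    stop_bindsig("need n >= 4 on both sides", class = "bindsig_stat_error")
  if (sd1 >= sd2) { big_n <- n1; small_n <- n2 } else { big_n <- n2; small_n <- n1 }
  f <- (max(sd1, sd2) / min(sd1, sd2))^2
  df1 <- big_n - 2L; df2 <- small_n - 2L
  p1 <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(f = f, df1 = df1, df2 = df2,
       p = if (alternative == "one.sided") p1 else min(1, 2 * p1))
}

#' Per-split evaluation report
#'
#' @param observed,predicted numeric vectors of pAffinity values.
#' @param label optional name for the split.
#' @return a \code{csm_evaluation}: list with \code{label}, \code{n},
#'   \code{pearson_r}, \code{spearman_rho}, \code{residual_sd}.
#' @export
evaluation_report <- function(observed, predicted, label = "split") {
  structure(list(label = label,
                 n = length(observed),
                 pearson_r = pearson_r(observed, predicted),
                 spearman_rho = spearman_rho(observed, predicted),
                 residual_sd = residual_sd(predicted, observed)),
            class = "csm_evaluation")
}

#' @export
print.csm_evaluation <- function(x, ...) {
  cat(sprintf("<csm_evaluation '%s': n = %d, Pearson r = %.3f, Spearman rho = %.3f, SD = %.3f>\n",
              x$label, x$n, x$pearson_r, x$spearman_rho, x$residual_sd))
  invisible(x)
}

#' Pairwise significance comparison of two methods
#'
#' Compares correlations by Fisher r-to-z (two-sided) and residual SDs by
#' the F-test (one-sided by default).
#'
#' @param r_a,sd_a,n_a correlation, residual SD and sample size of method A.
#' @param r_b,sd_b,n_b the same for method B.
#' @param labels length-2 character vector naming the methods.
#' @param f_alternative sidedness of the F-test.
#' @return one-row data frame: \code{method_a, method_b, fisher_z,
#'   fisher_p, f_stat, f_p}.
#' @export
compare_methods <- function(r_a, sd_a, n_a, r_b, sd_b, n_b,
                            labels = c("A", "B"),
                            f_alternative = "one.sided") {
  fz <- fisher_r_to_z(r_a, n_a, r_b, n_b)
  ft <- f_test_sd(sd_a, n_a, sd_b, n_b, alternative = f_alternative)
  data.frame(method_a = labels[1], method_b = labels[2],
             fisher_z = fz$z, fisher_p = fz$p,
             f_stat = ft$f, f_p = ft$p,
             stringsAsFactors = FALSE)
}
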