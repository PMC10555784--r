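#' Correct an effect estimate for regression dilution
#'
#' Multiplies the uncorrected coefficient (a difference in means, log odds,
#' logit or log hazard) by the correction factor lambda = 1/ICC.
#'
#' @param beta Uncorrected coefficient on the linear/log scale.
#' @param lambda Correction factor (> 0).
#' @return Corrected coefficient lambda * beta.
#' @export
#' @examples
#' exp(correct_estimate(log(1.203), 1.9356))  # corrected hazard ratio
correct_estimate <- function(beta, lambda) {
  check_number(beta, "beta")
  check_number(lambda, "lambda")
  if (lambda <= 0) abort("`lambda` must be > 0.")
  lambda * beta
}

#' Frost-Thompson confidence interval for a dilution-corrected estimate
#'
#' Propagates the uncertainty of both the uncorrected coefficient and the
#' correction factor via the quadratic-root construction
#' f0 = beta^2 - z^2 var(beta);
#' f1 = beta/lambda - z^2 cov(beta, 1/lambda);
#' f2 = 1/lambda^2 - z^2 var(1/lambda);
#' CI for the corrected coefficient = (f1 +/- sqrt(f1^2 - f0 f2)) / f2.
#' The covariance is 0 when the repeat-measure sample is disjoint from (or a
#' small subset of) the main analysis sample, which is the default.
#'
#' @param beta Uncorrected coefficient.
#' @param var_beta Sampling variance of `beta` (>= 0).
#' @param lambda Correction factor (> 0).
#' @param var_inv_lambda Sampling variance of 1/lambda (= var of the ICC
#'   estimate; >= 0).
#' @param cov_beta_inv_lambda Covariance of `beta` and 1/lambda (default 0).
#' @param z Normal quantile for the confidence level (default 1.96).
#' @return Object of class `"corrected_estimate"` with the corrected
#'   coefficient, interval bounds, and the f0/f1/f2 diagnostics.
#' @export
#' @examples
#' frost_ci(log(1.203), ((log(1.212) - log(1.194)) / (2 * 1.96))^2,
#'          lambda = 1.9356, var_inv_lambda = 0.000029)
frost_ci <- function(beta, var_beta, lambda, var_inv_lambda,
                     cov_beta_inv_lambda = 0, z = 1.96) {
  check_number(beta, "beta")
  check_number(var_beta, "var_beta", lower = 0)
  check_number(lambda, "lambda")
  check_number(var_inv_lambda, "var_inv_lambda", lower = 0)
  check_number(z, "z")
  if (lambda <= 0) abort("`lambda` must be > 0.")
  if (z <= 0) abort("`z` must be > 0.")

  f0 <- beta^2 - z^2 * var_beta
  f1 <- beta / lambda - z^2 * cov_beta_inv_lambda
  f2 <- 1 / lambda^2 - z^2 * var_inv_lambda
  if (f2 <= 0) {
    abort("correction factor too imprecise: f2 <= 0.",
          class = "undilute_frost_imprecise")
  }
  disc <- f1^2 - f0 * f2
  # zero-variance limit yields an exact-zero discriminant up to rounding
  if (disc < 0 && disc > -1e-12 * max(f1^2, 1e-300)) disc <- 0
  if (disc < 0) {
    abort("confidence interval undefined for these inputs (negative discriminant).",
          class = "undilute_frost_discriminant")
  }
  root <- sqrt(disc)
  structure(
    list(estimate = lambda * beta,
         conf.low = (f1 - root) / f2, conf.high = (f1 + root) / f2,
         f0 = f0, f1 = f1, f2 = f2, discriminant = disc,
         beta = beta, var_beta = var_beta, lambda = lambda,
         var_inv_lambda = var_inv_lambda, z = z, scale = "linear"),
    class = "corrected_estimate"
  )
}

#' Correct a ratio-scale estimate (hazard ratio, odds ratio) with its CI
#'
#' Converts the ratio and its confidence interval to the log scale (the
#' variance is recovered from the interval width as
#' ((log U - log L) / (2 z))^2), applies [correct_estimate()] and
#' [frost_ci()], and exponentiates back.
#'
#' @param ratio Uncorrected ratio estimate (> 0).
#' @param lower,upper Confidence bounds of the uncorrected ratio
#'   (0 < lower < upper).
#' @param lambda,var_inv_lambda,cov_beta_inv_lambda,z As in [frost_ci()].
#' @return A `"corrected_estimate"` on the ratio scale.
#' @export
#' @examples
#' correct_ratio_measure(1.203, 1.194, 1.212,
#'                       lambda = 1.9356, var_inv_lambda = 0.000029)
correct_ratio_measure <- function(ratio, lower, upper, lambda, var_inv_lambda,
                                  cov_beta_inv_lambda = 0, z = 1.96) {
  check_number(ratio, "ratio")
  if (ratio <= 0) abort("`ratio` must be > 0.")
  if (!(lower > 0 && lower < upper)) abort("need 0 < lower < upper.")
  beta <- log(ratio)
  var_beta <- ((log(upper) - log(lower)) / (2 * z))^2
  out <- frost_ci(beta, var_beta, lambda, var_inv_lambda,
                  cov_beta_inv_lambda, z)
  out$estimate <- exp(out$estimate)
  out$conf.low <- exp(out$conf.low)
  out$conf.high <- exp(out$conf.high)
  out$scale <- "ratio"
  out
}

#' @export
print.corrected_estimate <- function(x, digits = 4, ...) {
  lab <- if (x$scale == "ratio") "ratio" else "coefficient"
  cat(sprintf("<corrected_estimate>  corrected %s = %.*f  [%.*f, %.*f]\n",
              lab, digits, x$estimate, digits, x$conf.low, digits, x$conf.high))
  cat(sprintf("  lambda = %.4f   f0 = %.3g  f1 = %.3g  f2 = %.3g\n",
              x$lambda, x$f0, x$f1, x$f2))
  invisible(x)
}
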