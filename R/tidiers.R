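#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an agreement result
#'
#' @param x An [agreement()] result.
#' @param ... Unused.
#' @return One row per statistic: `term`, `estimate` (plus `conf.low` /
#'   `conf.high` for the ICC).
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble(
    term = c("icc", "accuracy", "lambda", "var_lambda", "var_inv_lambda"),
    estimate = c(x$icc, x$accuracy, x$lambda, x$var_lambda, x$var_inv_lambda),
    conf.low = c(x$conf.low, NA, NA, NA, NA),
    conf.high = c(x$conf.high, NA, NA, NA, NA)
  )
}

#' Glance at an agreement result
#'
#' @param x An [agreement()] result.
#' @param ... Unused.
#' @return A one-row tibble of the headline statistics.
#' @export
glance.agreement_result <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, icc = x$icc, conf.low = x$conf.low,
         conf.high = x$conf.high, convention = x$convention,
         accuracy = x$accuracy, lambda = x$lambda,
         var_lambda = x$var_lambda, var_inv_lambda = x$var_inv_lambda)
}

#' Tidy a corrected estimate
#'
#' @param x A [frost_ci()] / [correct_ratio_measure()] result.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, the f0/f1/f2
#'   diagnostics and the scale.
#' @export
tidy.corrected_estimate <- function(x, ...) {
  tibble(estimate = x$estimate, conf.low = x$conf.low, conf.high = x$conf.high,
         f0 = x$f0, f1 = x$f1, f2 = x$f2, discriminant = x$discriminant,
         lambda = x$lambda, scale = x$scale)
}

#' Tidy a second-stage model fit
#'
#' @param x A [fit_second_stage()] result.
#' @param ... Unused.
#' @return Coefficient table (`term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`).
#' @export
tidy.second_stage_fit <- function(x, ...) x$estimates

#' @export
glance.second_stage_fit <- function(x, ...) {
  tibble(family = x$family, nobs = stats::nobs(x$model), level = x$level)
}

#' Tidy a whole-process bootstrap result
#'
#' @param x A [bootstrap_calibration()] result.
#' @param ... Unused.
#' @return Coefficient table with bootstrap intervals.
#' @export
tidy.rc_boot <- function(x, ...) x$estimates

#' @export
glance.rc_boot <- function(x, ...) {
  tibble(family = x$family, reps = x$reps, used = x$used,
         skipped = x$skipped, ci = x$ci, level = x$level, seed = x$seed)
}
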