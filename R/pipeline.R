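#' Mortality (event) rate per 1000 person-years
#'
#' @param data Tibble with follow-up columns.
#' @param time,event Column names of the follow-up time (years) and the 0/1
#'   event indicator.
#' @param z Normal quantile for the confidence interval (default 1.96).
#' @param per Denominator scale (default 1000 person-years).
#' @param method `"lognormal"` (rate * exp(+/- z / sqrt(deaths)); default) or
#'   `"poisson"` (exact chi-square/Poisson quantile bounds).
#' @return One-row tibble: `events`, `person_years`, `rate`, `conf.low`,
#'   `conf.high`.
#' @export
#' @examples
#' person_years_rate(tibble::tibble(time = rep(100, 10), event = rep(1, 10)))
person_years_rate <- function(data, time = "time", event = "event", z = 1.96,
                              per = 1000, method = c("lognormal", "poisson")) {
  method <- match.arg(method)
  tt <- data[[time]]
  ee <- data[[event]]
  if (any(tt <= 0, na.rm = TRUE)) abort("follow-up times must be > 0.")
  if (!all(ee %in% c(0, 1, NA))) abort("`event` must be 0/1.")
  keep <- !is.na(tt) & !is.na(ee)
  d <- sum(ee[keep])
  py <- sum(tt[keep])
  if (py <= 0) abort("zero person-years.")
  rate <- per * d / py
  if (method == "lognormal") {
    lo <- rate * exp(-z / sqrt(d))
    hi <- rate * exp(z / sqrt(d))
  } else {
    alpha <- 2 * stats::pnorm(-z)   # z expressed back as a coverage level
    lo <- per * stats::qchisq(alpha / 2, 2 * d) / 2 / py
    hi <- per * stats::qchisq(1 - alpha / 2, 2 * (d + 1)) / 2 / py
  }
  tibble(events = d, person_years = py, rate = rate,
         conf.low = lo, conf.high = hi)
}

#' Screen a cohort and catalogue agreement for every eligible variable
#'
#' Applies the eligibility screen, then computes the full agreement analysis
#' (ICC with confidence interval, accuracy coefficient, correction factor and
#' its variances) for each included variable. Mirrors the structure of a
#' repeat-measures catalogue: one row per variable.
#'
#' @param cohort Wide cohort tibble.
#' @param convention,level,boot,seed Passed to [agreement()]; each variable's
#'   bootstrap is seeded deterministically from `seed`.
#' @param categories Optional named character vector mapping variable name to
#'   a category label (adds a `category` column, enabling
#'   [summarize_categories()]).
#' @param threshold_policy Passed to [screen_variables()].
#' @return Object of class `"agreement_scan"`: `catalogue` (one row per
#'   included variable), `exclusions`, and `decisions`.
#' @export
run_agreement_scan <- function(cohort, convention = c("agreement", "consistency"),
                               level = 0.95, boot = 1000, seed = 1L,
                               categories = NULL,
                               threshold_policy = c("boundary", "missing")) {
  convention <- match.arg(convention)
  threshold_policy <- match.arg(threshold_policy)
  decisions <- screen_variables(cohort, threshold_policy)
  included <- decisions$variable[decisions$verdict == "include"]
  if (length(included) == 0) abort("no variables pass the eligibility screen.")
  catalogue <- purrr::imap_dfr(stats::setNames(included, included), function(v, nm) {
    x1 <- coerce_threshold_codes(cohort[[occ1(v)]], threshold_policy)
    x2 <- coerce_threshold_codes(cohort[[occ2(v)]], threshold_policy)
    pm <- paired_measures(x1, x2)
    a <- agreement(pm, convention = convention, level = level, boot = boot,
                   seed = (seed + which(included == v)) %% .Machine$integer.max)
    tibble(variable = v, n = a$n_pairs, accuracy = a$accuracy,
           icc = a$icc, conf.low = a$conf.low, conf.high = a$conf.high,
           lambda = a$lambda, var_lambda = a$var_lambda,
           var_inv_lambda = a$var_inv_lambda, flag = a$icc_flag)
  })
  if (!is.null(categories)) {
    catalogue$category <- unname(categories[catalogue$variable])
  }
  structure(
    list(catalogue = catalogue,
         exclusions = dplyr::filter(as_tibble(decisions), .data$verdict == "exclude"),
         decisions = decisions, convention = convention, seed = seed),
    class = "agreement_scan"
  )
}

#' @export
print.agreement_scan <- function(x, ...) {
  cat(sprintf("<agreement_scan>  %d included, %d excluded (convention: %s)\n",
              nrow(x$catalogue), nrow(x$exclusions), x$convention))
  print(x$catalogue)
  invisible(x)
}

#' Compare uncorrected and dilution-corrected exposure-outcome estimates
#'
#' Produces the standard four-model comparison for one exposure:
#' \describe{
#'   \item{(i) uncorrected}{outcome model on the observed occasion-1 values,
#'     Wald confidence interval;}
#'   \item{(ii) ICC-corrected}{the model-(i) exposure coefficient multiplied
#'     by the correction factor 1/ICC, Frost-Thompson interval;}
#'   \item{(iii) regression calibration, exposure only}{two-stage calibration
#'     of the exposure, whole-process bootstrap percentile interval;}
#'   \item{(iv) regression calibration, exposure + confounders}{as (iii) but
#'     also calibrating every error-prone continuous confounder.}
#' }
#' For the cox/logistic families estimates are reported on the ratio scale.
#'
#' @param cohort Wide cohort tibble.
#' @param roles A [covariable_roles()] tibble; `error_prone` lists the
#'   exposure and any error-prone confounders used by model (iv).
#' @param family `"linear"`, `"logistic"` or `"cox"`.
#' @param reps Bootstrap replicates for models (iii)-(iv) (reference scale
#'   10000).
#' @param boot Bootstrap resamples for the ICC variance of model (ii).
#' @param seed Integer seed; the whole comparison is deterministic given it.
#' @param level Confidence level.
#' @return A tibble of class `"rdb_comparison"`: `model`, `label`,
#'   `estimate`, `conf.low`, `conf.high` (+ attribute `"scale"`).
#' @export
run_corrected_analysis <- function(cohort, roles,
                                   family = c("cox", "linear", "logistic"),
                                   reps = 1000, boot = 1000, seed = 1L,
                                   level = 0.95) {
  family <- match.arg(family)
  stopifnot(sum(roles$role == "exposure") == 1)
  exposure <- roles$name[roles$role == "exposure"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  ratio <- family %in% c("cox", "logistic")
  tr <- if (ratio) exp else identity

  # (i) uncorrected
  fit1 <- fit_second_stage(cohort, roles, family, level)
  row1 <- dplyr::filter(fit1$estimates, .data$term == fit1$exposure_term)

  # (ii) ICC correction of the exposure coefficient
  ag <- agreement(extract_pairs(cohort, exposure), boot = boot, seed = seed)
  fr <- frost_ci(row1$estimate, row1$std.error^2, ag$lambda,
                 ag$var_inv_lambda, z = z)

  # (iii) calibrate the exposure only
  roles_iii <- roles
  roles_iii$error_prone <- roles$name == exposure
  b3 <- bootstrap_calibration(cohort, roles_iii, family, reps = reps,
                              seed = seed, level = level)
  row3 <- dplyr::filter(b3$estimates, .data$term == b3$exposure_term)

  # (iv) calibrate exposure + error-prone confounders
  b4 <- bootstrap_calibration(cohort, roles, family, reps = reps,
                              seed = (seed + 1) %% .Machine$integer.max,
                              level = level)
  row4 <- dplyr::filter(b4$estimates, .data$term == b4$exposure_term)

  out <- tibble(
    model = c("i", "ii", "iii", "iv"),
    label = c("uncorrected",
              "ICC-corrected exposure",
              "regression calibration, exposure",
              "regression calibration, exposure + confounders"),
    estimate = tr(c(row1$estimate, fr$estimate, row3$estimate, row4$estimate)),
    conf.low = tr(c(row1$conf.low, fr$conf.low, row3$conf.low, row4$conf.low)),
    conf.high = tr(c(row1$conf.high, fr$conf.high, row3$conf.high, row4$conf.high))
  )
  class(out) <- c("rdb_comparison", class(out))
  attr(out, "scale") <- if (ratio) "ratio" else "linear"
  attr(out, "exposure") <- exposure
  attr(out, "family") <- family
  attr(out, "agreement") <- ag
  out
}
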