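#' Declare covariable roles for a calibration analysis
#'
#' @param exposure Name of the single exposure variable.
#' @param confounders Character vector of confounder names.
#' @param error_prone Names of covariables measured with random error that
#'   should be calibrated (must be continuous and have repeat measures in the
#'   cohort). Defaults to the exposure only.
#' @param categorical Names of categorical confounders (assumed error-free;
#'   entered as indicator contrasts with the first observed level as
#'   reference).
#' @return Tibble with columns `name`, `role`, `error_prone`, `scale`
#'   (class `"covariable_roles"`).
#' @export
#' @examples
#' covariable_roles("crp", confounders = c("bmi", "sex"),
#'                  error_prone = c("crp", "bmi"), categorical = "sex")
covariable_roles <- function(exposure, confounders = character(),
                             error_prone = exposure,
                             categorical = character()) {
  stopifnot(length(exposure) == 1)
  name <- c(exposure, confounders)
  if (anyDuplicated(name)) abort("covariable names must be unique.")
  if (!all(error_prone %in% name)) {
    abort("`error_prone` names must be among the exposure/confounders.")
  }
  if (any(error_prone %in% categorical)) {
    abort("error-prone covariables must be continuous, not categorical.")
  }
  out <- tibble(
    name = name,
    role = c("exposure", rep("confounder", length(confounders))),
    error_prone = name %in% error_prone,
    scale = ifelse(name %in% categorical, "categorical", "continuous")
  )
  class(out) <- c("covariable_roles", class(out))
  out
}

# design column in the cohort for a covariable: occasion-1 column if present,
# else the plain column (categorical confounders, error-free numerics)
.design_col <- function(cohort, nm) {
  if (occ1(nm) %in% names(cohort)) occ1(nm) else if (nm %in% names(cohort)) nm
  else abort(sprintf("cohort has no column for covariable '%s'.", nm))
}

# data frame of first-stage regressors: target occasion-1 plus the other
# covariables (occasion-1 values; categoricals as factors)
.fs_frame <- function(cohort, target, covariables) {
  df <- tibble(.target = cohort[[.design_col(cohort, target)]])
  for (nm in covariables) df[[nm]] <- cohort[[.design_col(cohort, nm)]]
  df
}

#' Fit a first-stage calibration model for one error-prone covariable
#'
#' Ordinary least squares of the occasion-2 (repeat) measure of the target on
#' its occasion-1 measure plus all other covariables of the main model
#' (occasion-1 values; categorical covariables as indicator contrasts),
#' complete cases within the repeat subsample. Under the classical error
#' model, E(occasion-2 | occasion-1) has slope equal to the reliability, so
#' the fitted values are the calibrated (error-corrected) covariable.
#'
#' @param cohort Wide cohort tibble.
#' @param target Name of the error-prone covariable being calibrated.
#' @param covariables Names of the other covariables of the main model.
#' @return Object of class `"calibration_fit"` with the coefficients and
#'   `n_used`.
#' @export
fit_first_stage <- function(cohort, target, covariables = character()) {
  if (!occ2(target) %in% names(cohort)) {
    abort(sprintf("'%s' has no occasion-2 column: cannot calibrate.", target))
  }
  df <- .fs_frame(cohort, target, covariables)
  df$.y <- cohort[[occ2(target)]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p <- ncol(df)  # regressors + response ~ minimal sample size guard
  if (nrow(df) < p + 1) {
    abort(sprintf("too few complete repeat rows (%d) to fit the first-stage model for '%s'.",
                  nrow(df), target))
  }
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("first-stage design is rank deficient; collinear columns: %s.",
                  paste(names(cf)[is.na(cf)], collapse = ", ")),
          class = "undilute_rank_deficient")
  }
  names(cf)[names(cf) == ".target"] <- occ1(target)
  structure(
    list(target = target, covariables = covariables, model = fit,
         coefficients = cf, n_used = nrow(df)),
    class = "calibration_fit"
  )
}

#' Predict calibrated values for all participants
#'
#' Applies the first-stage coefficients to every participant's occasion-1
#' data (including participants without repeat measures). Being OLS fitted
#' values, their variance never exceeds the variance of the observed
#' occasion-1 values.
#'
#' @param fit A [fit_first_stage()] result.
#' @param cohort Wide cohort tibble carrying every covariable used in `fit`.
#' @return Numeric vector of calibrated values, one per row of `cohort`.
#' @export
predict_calibrated <- function(fit, cohort) {
  stopifnot(inherits(fit, "calibration_fit"))
  newdata <- .fs_frame(cohort, fit$target, fit$covariables)
  as.numeric(stats::predict(fit$model, newdata = newdata))
}

#' Calibrate every error-prone covariable of a cohort
#'
#' Runs one first-stage model per error-prone covariable — each adjusted for
#' all other covariables at their observed occasion-1 values (simultaneous,
#' not iterated) — and replaces the covariable's occasion-1 column with its
#' calibrated predictions. Error-free and categorical covariables are
#' untouched.
#'
#' @param cohort Wide cohort tibble.
#' @param roles A [covariable_roles()] tibble.
#' @return The cohort with calibrated `<var>__i1` columns; fitted first-stage
#'   models in attribute `"calibration_fits"`.
#' @export
calibrate_cohort <- function(cohort, roles) {
  stopifnot(inherits(roles, "covariable_roles") || is.data.frame(roles))
  targets <- roles$name[roles$error_prone]
  for (t in targets) {
    if (!occ2(t) %in% names(cohort) || !any(!is.na(cohort[[occ2(t)]]))) {
      abort(sprintf("error-prone covariable '%s' has no repeat measures.", t))
    }
  }
  fits <- purrr::map(targets, function(t) {
    fit_first_stage(cohort, t, covariables = setdiff(roles$name, t))
  })
  names(fits) <- targets
  out <- cohort
  for (t in targets) out[[occ1(t)]] <- predict_calibrated(fits[[t]], cohort)
  if (length(fits)) attr(out, "calibration_fits") <- fits
  out
}

# outcome columns demanded by each family
.check_outcome <- function(cohort, family) {
  need <- if (family == "cox") c("time", "event") else "y"
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort lacks outcome column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (family == "logistic" && !all(cohort$y %in% c(0, 1, NA))) {
    abort("logistic family needs a 0/1 outcome `y`.")
  }
  invisible(NULL)
}

#' Fit the second-stage (main) outcome model
#'
#' Standard maximum-(partial-)likelihood fit of the outcome on the cohort's
#' covariable columns — calibrated or not, whichever the cohort carries.
#'
#' @param cohort Wide cohort tibble (typically from [calibrate_cohort()]).
#' @param roles A [covariable_roles()] tibble.
#' @param family `"linear"`, `"logistic"` or `"cox"`. Outcome columns: `y`
#'   for linear/logistic, `time` + `event` for cox.
#' @param level Confidence level for the Wald intervals.
#' @return Object of class `"second_stage_fit"` wrapping the fitted model and
#'   a tidy coefficient table.
#' @export
fit_second_stage <- function(cohort, roles, family = c("linear", "logistic", "cox"),
                             level = 0.95) {
  family <- match.arg(family)
  .check_outcome(cohort, family)
  terms <- vapply(roles$name, function(nm) .design_col(cohort, nm), character(1))
  rhs <- paste(sprintf("`%s`", terms), collapse = " + ")
  fit <- switch(
    family,
    linear = stats::lm(stats::as.formula(paste("y ~", rhs)), data = cohort),
    logistic = stats::glm(stats::as.formula(paste("y ~", rhs)),
                          family = stats::binomial(), data = cohort),
    cox = survival::coxph(
      stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
      data = cohort)
  )
  if (family != "cox" && !isTRUE(fit$converged %||% TRUE)) {
    abort("second-stage model did not converge.")
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  keep <- names(cf) != "(Intercept)"
  est <- tibble(
    term = names(cf)[keep], estimate = unname(cf[keep]),
    std.error = unname(se[keep]),
    conf.low = unname(cf[keep] - z * se[keep]),
    conf.high = unname(cf[keep] + z * se[keep])
  )
  structure(
    list(model = fit, family = family, level = level, estimates = est,
         exposure_term = unname(terms[roles$role == "exposure"][1])),
    class = "second_stage_fit"
  )
}

#' @export
print.second_stage_fit <- function(x, ...) {
  cat(sprintf("<second_stage_fit>  family = %s\n", x$family))
  print(x$estimates)
  invisible(x)
}

# ---- matrix engine shared by point estimation and the bootstrap ------------

# Precompute the design machinery once so each bootstrap replicate is a pair
# of matrix least-squares / partial-likelihood fits, not a tibble pipeline.
.rc_engine <- function(cohort, roles, family) {
  .check_outcome(cohort, family)
  n_all <- nrow(cohort)
  cols <- list(`(Intercept)` = rep(1, n_all))
  colmap <- list()
  for (i in seq_len(nrow(roles))) {
    nm <- roles$name[i]
    src <- .design_col(cohort, nm)
    if (roles$scale[i] == "categorical") {
      f <- cohort[[src]]
      if (!is.factor(f)) f <- factor(f)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      # model.matrix drops NA rows; rebuild with NA padding
      mm_full <- matrix(NA_real_, n_all, ncol(mm),
                        dimnames = list(NULL, paste0(nm, levels(f)[-1])))
      mm_full[!is.na(f), ] <- mm
      for (j in seq_len(ncol(mm_full))) cols[[colnames(mm_full)[j]]] <- mm_full[, j]
      colmap[[nm]] <- colnames(mm_full)
    } else {
      cols[[src]] <- as.numeric(cohort[[src]])
      colmap[[nm]] <- src
    }
  }
  M <- do.call(cbind, cols)
  targets <- roles$name[roles$error_prone]
  t2 <- lapply(targets, function(t) as.numeric(cohort[[occ2(t)]]))
  names(t2) <- targets
  if (family == "cox") {
    yy <- cbind(time = cohort$time, event = cohort$event)
  } else {
    yy <- cbind(y = cohort$y)
  }
  cc <- stats::complete.cases(M) & stats::complete.cases(yy)
  M <- M[cc, , drop = FALSE]
  yy <- yy[cc, , drop = FALSE]
  t2 <- lapply(t2, function(v) v[cc])
  tgt_cols <- vapply(targets, function(t) match(colmap[[t]], colnames(M)), integer(1))
  term_names <- setdiff(colnames(M), "(Intercept)")
  list(M = M, y = yy, t2 = t2, targets = targets, tgt_cols = tgt_cols,
       n = nrow(M), p = ncol(M), family = family, term_names = term_names)
}

# one calibrated fit on a row subset; returns named coefficients or NULL (skip)
.rc_replicate <- function(eng, rows) {
  Ms <- eng$M[rows, , drop = FALSE]
  X2 <- Ms
  for (i in seq_along(eng$targets)) {
    yr <- eng$t2[[i]][rows]
    obs <- !is.na(yr)
    if (sum(obs) < eng$p + 1) return(NULL)
    fs <- stats::lm.fit(Ms[obs, , drop = FALSE], yr[obs])
    cf <- fs$coefficients
    if (fs$rank < eng$p || anyNA(cf)) return(NULL)
    X2[, eng$tgt_cols[i]] <- drop(Ms %*% cf)
  }
  keep <- colnames(X2) != "(Intercept)"
  if (eng$family == "linear") {
    fit <- stats::lm.fit(X2, eng$y[rows, "y"])
    cf <- fit$coefficients
    if (fit$rank < eng$p || anyNA(cf)) return(NULL)
    cf[keep]
  } else if (eng$family == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(X2, eng$y[rows, "y"], family = stats::binomial()))
    cf <- stats::coef(fit)
    cf[keep]
  } else {
    X <- X2[, keep, drop = FALSE]
    fit <- survival::coxph(
      survival::Surv(eng$y[rows, "time"], eng$y[rows, "event"]) ~ X,
      ties = "efron")
    cf <- stats::coef(fit)
    names(cf) <- colnames(X)
    cf
  }
}

#' Whole-process bootstrap for two-stage regression calibration
#'
#' Resamples participants with replacement from the full cohort; within each
#' replicate every first-stage calibration model is refit on the replicate's
#' repeat subsample and the second-stage outcome model on the whole
#' replicate, so the confidence intervals reflect the sampling variability of
#' both stages jointly. Intervals are percentile by default (2.5/97.5 for
#' `level = 0.95`); a normal approximation using the bootstrap standard error
#' is available.
#'
#' Replicates whose repeat subsample is too small (or rank deficient) are
#' skipped and counted; more than 10% skipped is an error.
#'
#' @param cohort Wide cohort tibble.
#' @param roles A [covariable_roles()] tibble.
#' @param family `"linear"`, `"logistic"` or `"cox"`.
#' @param reps Number of bootstrap replicates (>= 2; the reference analysis
#'   scale is 10000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param level Confidence level.
#' @param ci `"percentile"` or `"normal"`.
#' @return Object of class `"rc_boot"`: point estimates (from the full
#'   cohort), bootstrap intervals per coefficient, and the replicate
#'   estimates.
#' @export
bootstrap_calibration <- function(cohort, roles, family = c("linear", "logistic", "cox"),
                                  reps = 1000, seed = 1L, level = 0.95,
                                  ci = c("percentile", "normal")) {
  family <- match.arg(family)
  ci <- match.arg(ci)
  if (reps < 2) abort("`reps` must be >= 2.")
  eng <- .rc_engine(cohort, roles, family)
  point <- .rc_replicate(eng, seq_len(eng$n))
  if (is.null(point)) abort("full-sample calibration failed (repeat subsample too small or design rank deficient).")

  draws <- matrix(NA_real_, reps, length(point))
  skipped <- 0L
  local_seed(seed, {
    for (r in seq_len(reps)) {
      rows <- sample.int(eng$n, eng$n, replace = TRUE)
      est <- .rc_replicate(eng, rows)
      if (is.null(est)) skipped <- skipped + 1L else draws[r, ] <- est
    }
  })
  if (skipped > 0.10 * reps) {
    abort(sprintf("%d of %d bootstrap replicates unusable (>10%%).",
                  skipped, reps), class = "undilute_boot_failed")
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  alpha <- 1 - level
  if (ci == "percentile") {
    lo <- apply(draws, 2, stats::quantile, probs = alpha / 2, names = FALSE)
    hi <- apply(draws, 2, stats::quantile, probs = 1 - alpha / 2, names = FALSE)
  } else {
    se <- apply(draws, 2, stats::sd)
    z <- stats::qnorm(1 - alpha / 2)
    lo <- point - z * se
    hi <- point + z * se
  }
  est <- tibble(term = names(point), estimate = unname(point),
                conf.low = lo, conf.high = hi)
  colnames(draws) <- names(point)
  structure(
    list(estimates = est, replicates = as_tibble(draws),
         reps = reps, used = nrow(draws), skipped = skipped,
         family = family, level = level, ci = ci, seed = seed,
         exposure_term = {
           eterm <- roles$name[roles$role == "exposure"][1]
           if (occ1(eterm) %in% est$term) occ1(eterm) else eterm
         }),
    class = "rc_boot"
  )
}

#' @export
print.rc_boot <- function(x, ...) {
  cat(sprintf("<rc_boot>  family = %s | %d replicates (%d used, %d skipped) | %s CI\n",
              x$family, x$reps, x$used, x$skipped, x$ci))
  print(x$estimates)
  invisible(x)
}
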