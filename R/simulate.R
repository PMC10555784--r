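#' Describe the continuous covariables of a synthetic cohort
#'
#' Builds the per-variable block of a [sim_config()]: one row per continuous
#' covariable with its latent (true) distribution, test-retest reliability,
#' any systematic shift applied at the second measurement occasion, its role
#' in the analysis model, and its effect on the outcome.
#'
#' @param name Character vector of variable names.
#' @param mean,sd Latent true means and standard deviations (recycled).
#' @param reliability Reliability ratio R = var(truth) / var(observed), in
#'   (0, 1]. Under the classical error model the ICC of two occasions equals R.
#' @param shift Additive systematic difference applied to occasion-2
#'   measurements only (default 0). A non-zero shift leaves the ICC's target
#'   largely intact but drives Lin's accuracy coefficient below 1.
#' @param role One of `"exposure"`, `"confounder"`, `"noise"`.
#' @param beta True per-unit effect on the outcome's linear predictor
#'   (log-hazard for the Cox family, mean shift for the linear family).
#' @return A tibble with one row per variable.
#' @export
#' @examples
#' sim_variables(c("crp", "bmi"), mean = c(2, 27), sd = c(4, 4.8),
#'               reliability = c(0.3, 0.93), beta = c(0.03, 0.02))
sim_variables <- function(name, mean = 0, sd = 1, reliability = 1, shift = 0,
                          role = "confounder", beta = 0) {
  tibble(
    name = as.character(name), mean = as.numeric(mean), sd = as.numeric(sd),
    reliability = as.numeric(reliability), shift = as.numeric(shift),
    role = as.character(role), beta = as.numeric(beta)
  )
}

#' Describe a categorical (error-free) confounder
#'
#' @param name Variable name.
#' @param levels Character vector of level labels.
#' @param probs Marginal level probabilities; must sum to 1.
#' @param log_hazards Per-level additive contribution to the outcome linear
#'   predictor (first level is conventionally the reference, 0).
#' @return A list describing the confounder, for `categorical` in
#'   [sim_config()].
#' @export
sim_categorical <- function(name, levels, probs, log_hazards = rep(0, length(levels))) {
  if (length(levels) != length(probs) || length(levels) != length(log_hazards)) {
    abort("`levels`, `probs` and `log_hazards` must have equal length.")
  }
  if (abs(sum(probs) - 1) > 1e-8) abort("`probs` must sum to 1.")
  list(name = name, levels = as.character(levels), probs = as.numeric(probs),
       log_hazards = as.numeric(log_hazards))
}

#' Describe the outcome model of a synthetic cohort
#'
#' @param family `"cox"` for right-censored survival times from a
#'   proportional-hazards model with constant baseline hazard, or `"linear"`
#'   for a Gaussian outcome.
#' @param baseline_hazard Baseline hazard rate (events per person-year) for
#'   the Cox family. Ignored when `target_event_fraction` is given.
#' @param horizon Administrative censoring horizon in years; all follow-up
#'   times lie in (0, horizon].
#' @param target_event_fraction Optional; when set, the baseline hazard is
#'   calibrated so the expected event fraction equals this value.
#' @param uniform_censor_max Optional; when set, an independent uniform(0,
#'   `uniform_censor_max`) censoring time is applied in addition to the
#'   administrative horizon.
#' @param residual_sd Residual standard deviation for the linear family.
#' @return A list describing the outcome model.
#' @export
sim_outcome <- function(family = c("cox", "linear"), baseline_hazard = 0.02,
                        horizon = 15, target_event_fraction = NULL,
                        uniform_censor_max = NULL, residual_sd = 1) {
  family <- match.arg(family)
  check_number(horizon, "horizon")
  if (family == "cox" && horizon <= 0) abort("`horizon` must be > 0.")
  check_number(target_event_fraction, "target_event_fraction", 0, 1, allow_null = TRUE)
  list(family = family, baseline_hazard = baseline_hazard, horizon = horizon,
       target_event_fraction = target_event_fraction,
       uniform_censor_max = uniform_censor_max, residual_sd = residual_sd)
}

#' Configure a synthetic cohort with known measurement error
#'
#' The generator emulates a prospective cohort in which every continuous
#' covariable is observed under classical additive error at a configured
#' reliability, a fraction of participants attend a second measurement
#' occasion, and outcomes arise from a known model on the latent true values.
#' Because reliabilities, shifts and true effects are configured, every
#' downstream stage (agreement metrics, dilution correction, regression
#' calibration) can be validated against known truth.
#'
#' @param n Number of participants (>= 2).
#' @param variables Tibble from [sim_variables()].
#' @param repeat_fraction Fraction of participants with an occasion-2
#'   measurement (default 0.10), selected by seeded simple random sampling.
#' @param true_correlation Optional correlation matrix over the latent true
#'   values (symmetric positive-definite, unit diagonal). Default identity.
#' @param categorical List of [sim_categorical()] confounders.
#' @param outcome List from [sim_outcome()].
#' @param seed Integer seed; all generator output is bit-identical given the
#'   same config and seed.
#' @return A validated config object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(
#'   n = 500,
#'   variables = sim_variables("exposure", reliability = 0.5, role = "exposure",
#'                             beta = 0.3),
#'   outcome = sim_outcome("cox", target_event_fraction = 0.3),
#'   seed = 1
#' )
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n, variables, repeat_fraction = 0.10,
                       true_correlation = NULL, categorical = list(),
                       outcome = sim_outcome(), seed = 1L) {
  check_number(n, "n", lower = 2)
  check_number(repeat_fraction, "repeat_fraction", 0, 1)
  stopifnot(is.data.frame(variables), nrow(variables) >= 1)
  variables <- sim_variables(variables$name, variables$mean, variables$sd,
                             variables$reliability, variables$shift,
                             variables$role, variables$beta)
  if (anyDuplicated(variables$name)) abort("variable names must be unique.")
  if (any(variables$reliability <= 0 | variables$reliability > 1)) {
    abort("all reliabilities must lie in (0, 1].")
  }
  if (any(variables$sd < 0)) abort("true sds must be >= 0.")
  if (!all(variables$role %in% c("exposure", "confounder", "noise"))) {
    abort('roles must be "exposure", "confounder" or "noise".')
  }
  p <- nrow(variables)
  if (is.null(true_correlation)) true_correlation <- diag(p)
  true_correlation <- as.matrix(true_correlation)
  if (!isTRUE(all.equal(dim(true_correlation), c(p, p)))) {
    abort("`true_correlation` must be square with one row per variable.")
  }
  if (max(abs(true_correlation - t(true_correlation))) > 1e-10 ||
      max(abs(diag(true_correlation) - 1)) > 1e-10) {
    abort("`true_correlation` must be symmetric with unit diagonal.")
  }
  ev <- eigen(true_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort("`true_correlation` must be positive-definite.", class = "undilute_bad_correlation")
  }
  structure(
    list(n = as.integer(n), variables = variables,
         repeat_fraction = repeat_fraction, true_correlation = true_correlation,
         categorical = categorical, outcome = outcome, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n, "| repeat fraction =", x$repeat_fraction,
      "| outcome:", x$outcome$family, "| seed =", x$seed, "\n")
  print(x$variables)
  invisible(x)
}

# stage-specific seed offsets keep each operation independently deterministic
.seed_stage <- function(config, stage) {
  offsets <- c(truth = 101L, occ1 = 202L, occ2 = 303L, categorical = 404L,
               outcome = 505L, subsample = 606L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Draw the latent true covariable values
#'
#' Multivariate Gaussian with the configured marginal means/sds and the
#' configured correlation over variables (Cholesky factorisation).
#'
#' @param config A [sim_config()].
#' @return Tibble with `id` and one column per variable holding true values.
#' @export
generate_true_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variables
  p <- nrow(v)
  z <- local_seed(.seed_stage(config, "truth"),
                  matrix(stats::rnorm(config$n * p), ncol = p))
  x <- z %*% chol(config$true_correlation)
  x <- sweep(x, 2, v$sd, `*`)
  x <- sweep(x, 2, v$mean, `+`)
  colnames(x) <- v$name
  dplyr::bind_cols(tibble(id = seq_len(config$n)), as_tibble(x))
}

#' Apply classical measurement error to true values
#'
#' Implements the classical additive error model: observed = truth +
#' shift * 1\[occasion 2\] + e with e ~ Normal(0, sd^2 (1 - R) / R),
#' independent across occasions and of the truth. The reliability R is then
#' var(truth) / var(observed), and the two-occasion ICC converges to R.
#'
#' @param true_values Tibble from [generate_true_covariates()].
#' @param config A [sim_config()].
#' @param occasion 1 or 2; the configured `shift` is added at occasion 2 only,
#'   and each occasion uses an independent error draw.
#' @return Tibble of observed values, same shape as `true_values`.
#' @export
add_measurement_error <- function(true_values, config, occasion = 1) {
  stopifnot(inherits(config, "sim_config"), occasion %in% c(1, 2))
  v <- config$variables
  if (any(v$reliability <= 0)) abort("reliability must be > 0.")
  stage <- if (occasion == 1) "occ1" else "occ2"
  n <- nrow(true_values)
  err_sd <- v$sd * sqrt((1 - v$reliability) / v$reliability)
  e <- local_seed(.seed_stage(config, stage),
                  matrix(stats::rnorm(n * nrow(v)), ncol = nrow(v)))
  e <- sweep(e, 2, err_sd, `*`)
  obs <- as.matrix(true_values[, v$name, drop = FALSE]) + e
  if (occasion == 2) obs <- sweep(obs, 2, v$shift, `+`)
  dplyr::bind_cols(true_values["id"], as_tibble(obs))
}

# sample categorical confounder levels (independent of the continuous truths)
generate_categorical_levels <- function(config) {
  out <- tibble(id = seq_len(config$n))
  local_seed(.seed_stage(config, "categorical"), {
    for (cc in config$categorical) {
      out[[cc$name]] <- factor(
        sample(cc$levels, config$n, replace = TRUE, prob = cc$probs),
        levels = cc$levels
      )
    }
  })
  out
}

# linear predictor of the outcome model on the latent truths
.linear_predictor <- function(true_values, categorical, config) {
  v <- config$variables
  lp <- as.vector(as.matrix(true_values[, v$name, drop = FALSE]) %*% v$beta)
  for (cc in config$categorical) {
    lp <- lp + cc$log_hazards[match(categorical[[cc$name]], cc$levels)]
  }
  lp
}

#' Generate survival (or linear) outcomes from the latent truths
#'
#' For the Cox family, event times are exponential with hazard
#' h0 * exp(linear predictor) so proportional hazards hold exactly; follow-up
#' is administratively censored at the horizon, optionally also by an
#' independent uniform censoring time. When a target event fraction is
#' configured, h0 is calibrated so the expected event fraction matches it.
#' For the linear family, the outcome is Gaussian about the linear predictor.
#'
#' @param true_values Tibble from [generate_true_covariates()].
#' @param categorical Tibble of categorical levels (or NULL if none).
#' @param config A [sim_config()].
#' @return Tibble with `id` and either `time` (years) and `event` (0/1), or `y`.
#' @export
generate_survival <- function(true_values, categorical, config) {
  stopifnot(inherits(config, "sim_config"))
  out <- config$outcome
  n <- nrow(true_values)
  if (is.null(categorical)) categorical <- tibble(id = seq_len(n))
  lp <- .linear_predictor(true_values, categorical, config)

  if (out$family == "linear") {
    y <- local_seed(.seed_stage(config, "outcome"),
                    lp + stats::rnorm(n, 0, out$residual_sd))
    return(tibble(id = true_values$id, y = y))
  }

  if (out$horizon <= 0) abort("`horizon` must be > 0.")
  h0 <- out$baseline_hazard
  if (is.null(out$target_event_fraction) && (!is.numeric(h0) || h0 <= 0)) {
    abort("`baseline_hazard` must be > 0 (or set `target_event_fraction`).")
  }
  if (!is.null(out$target_event_fraction)) {
    # calibrate h0 so that E[1 - exp(-h0 e^lp * horizon)] = target
    target <- out$target_event_fraction
    f <- function(log_h) mean(1 - exp(-exp(log_h + lp) * out$horizon)) - target
    h0 <- exp(stats::uniroot(f, c(-40, 40), tol = 1e-12)$root)
  }
  rate <- h0 * exp(lp)
  local_seed(.seed_stage(config, "outcome"), {
    t_event <- stats::rexp(n, rate = rate)
    censor <- rep(out$horizon, n)
    if (!is.null(out$uniform_censor_max)) {
      censor <- pmin(censor, stats::runif(n, 0, out$uniform_censor_max))
    }
    tibble(id = true_values$id,
           time = pmax(pmin(t_event, censor), .Machine$double.eps),
           event = as.integer(t_event <= censor))
  })
}

#' Assemble the participant-level cohort table
#'
#' Joins the occasion-1 and occasion-2 observed values, categorical levels and
#' outcomes into the wide cohort layout (`<var>__i1` / `<var>__i2` columns)
#' and blanks occasion-2 values outside the seeded repeat subsample of exactly
#' `round(n * repeat_fraction)` participants.
#'
#' @param observed1,observed2 Tibbles from [add_measurement_error()] for
#'   occasions 1 and 2.
#' @param categorical Tibble of categorical levels, or NULL.
#' @param outcome Tibble from [generate_survival()].
#' @param config A [sim_config()].
#' @return A cohort tibble; the repeat-subsample ids are in attribute
#'   `"repeat_ids"`.
#' @export
assemble_cohort <- function(observed1, observed2, categorical, outcome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(observed1$id, observed2$id) ||
      !identical(observed1$id, outcome$id)) {
    abort("participant ids of the parts do not match.")
  }
  vars <- config$variables$name
  n <- nrow(observed1)
  n_rep <- round(n * config$repeat_fraction)
  rep_ids <- local_seed(.seed_stage(config, "subsample"),
                        sort(sample(observed1$id, n_rep)))
  o1 <- observed1[, vars, drop = FALSE]
  names(o1) <- occ1(vars)
  o2 <- observed2[, vars, drop = FALSE]
  o2[!(observed1$id %in% rep_ids), ] <- NA_real_
  names(o2) <- occ2(vars)
  # interleave __i1/__i2 per variable
  ord <- as.vector(rbind(occ1(vars), occ2(vars)))
  wide <- dplyr::bind_cols(o1, o2)[, ord]
  out <- dplyr::bind_cols(tibble(id = observed1$id), wide)
  if (!is.null(categorical) && ncol(categorical) > 1) {
    out <- dplyr::left_join(out, categorical, by = "id")
  }
  out <- dplyr::left_join(out, outcome, by = "id")
  attr(out, "repeat_ids") <- rep_ids
  out
}

#' Simulate a full cohort
#'
#' Runs [generate_true_covariates()], [add_measurement_error()] (both
#' occasions), [generate_survival()] and [assemble_cohort()] in sequence.
#'
#' @param config A [sim_config()].
#' @param keep_truth Keep the latent true values as attribute `"truth"`
#'   (useful for parameter-recovery checks).
#' @return A cohort tibble with attributes `"config"`, `"repeat_ids"` and
#'   optionally `"truth"`.
#' @export
simulate_cohort <- function(config, keep_truth = TRUE) {
  truth <- generate_true_covariates(config)
  obs1 <- add_measurement_error(truth, config, occasion = 1)
  obs2 <- add_measurement_error(truth, config, occasion = 2)
  cats <- if (length(config$categorical)) generate_categorical_levels(config)
  outc <- generate_survival(truth, cats, config)
  cohort <- assemble_cohort(obs1, obs2, cats, outc, config)
  attr(cohort, "config") <- config
  if (keep_truth) attr(cohort, "truth") <- truth
  cohort
}

#' Build a screening fixture with designed pathologies
#'
#' Constructs a wide two-occasion table containing, by design: an integer
#' variable with exactly 20 distinct values (fails the >20 distinct rule), an
#' integer variable with 26 distinct values (passes), a variable with >20%
#' of participants sharing one value, a variable with exactly 99 repeat pairs,
#' a threshold-coded character variable (values such as `"<=1"`), a variable
#' with no occasion-2 measurements, and two clean eligible variables. The
#' designed verdicts are attached as attribute `"expected"`.
#'
#' @param n Number of participants (default 400; must be >= 200).
#' @param seed Integer seed.
#' @return A wide tibble with `<var>__i1` / `<var>__i2` columns.
#' @export
generate_showcase_table <- function(n = 400, seed = 1L) {
  stopifnot(n >= 200)
  local_seed(seed, {
    rep_rows <- seq_len(n) <= round(n * 0.5)  # ample repeat pairs
    blank <- function(x, keep) replace(x, !keep, NA_real_)

    clean_a <- stats::rnorm(n, 50, 10)
    clean_b <- stats::rnorm(n)
    int_ok <- sample(0:25, n, replace = TRUE)             # 26 distinct
    few_distinct <- sample(seq_len(20), n, replace = TRUE) # exactly 20 distinct
    few_distinct[1:20] <- 1:20
    many_ties <- stats::rnorm(n)
    many_ties[seq_len(ceiling(0.25 * n))] <- 7.5          # 25% share one value
    sparse <- stats::rnorm(n)
    sparse2 <- blank(sparse + stats::rnorm(n, 0, 0.3), seq_len(n) <= 99)
    thresh_num <- stats::runif(n, 0.5, 30)
    as_code <- function(x) {
      out <- sprintf("%.2f", x)
      out[x <= 1] <- "<=1"
      out[x >= 29] <- ">=29"
      out
    }
    out <- tibble(
      id = seq_len(n),
      clean_a__i1 = clean_a,
      clean_a__i2 = blank(clean_a + stats::rnorm(n, 0, 3), rep_rows),
      clean_b__i1 = clean_b,
      clean_b__i2 = blank(clean_b + stats::rnorm(n, 0, 0.5), rep_rows),
      int_ok__i1 = int_ok,
      int_ok__i2 = blank(sample(0:25, n, replace = TRUE), rep_rows),
      few_distinct__i1 = few_distinct,
      few_distinct__i2 = blank(sample(seq_len(20), n, replace = TRUE), rep_rows),
      many_ties__i1 = many_ties,
      many_ties__i2 = blank(many_ties + stats::rnorm(n, 0, 0.3), rep_rows),
      sparse_repeat__i1 = sparse,
      sparse_repeat__i2 = sparse2,
      thresh__i1 = as_code(thresh_num),
      thresh__i2 = replace(as_code(pmin(pmax(thresh_num + stats::rnorm(n, 0, 1),
                                             0.2), 30)),
                           !rep_rows, NA_character_),
      no_repeat__i1 = stats::rnorm(n, 10, 2)
    )
    attr(out, "expected") <- tibble(
      variable = c("clean_a", "clean_b", "int_ok", "few_distinct", "many_ties",
                   "sparse_repeat", "thresh", "no_repeat"),
      verdict = c("include", "include", "include", "exclude", "exclude",
                  "exclude", "include", "exclude"),
      reason = c("ok", "ok", "ok", "not_continuous", "too_many_ties",
                 "too_few_repeats", "ok", "no_repeat")
    )
    out
  })
}
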