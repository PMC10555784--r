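test_that("first-stage model matches hand-solved normal equations", {
  # identity repeats: slope 1, intercept 0
  co <- tibble::tibble(x__i1 = c(1, 2, 4), x__i2 = c(1, 2, 4), y = c(0, 0, 0))
  fit <- fit_first_stage(co, "x")
  expect_equal(unname(fit$coefficients), c(0, 1))
  # 3-row toy against an explicit normal-equations solve
  co2 <- tibble::tibble(x__i1 = c(1, 2, 4), x__i2 = c(1.2, 1.9, 4.4))
  fit2 <- fit_first_stage(co2, "x")
  oracle <- normal_equations(cbind(1, co2$x__i1), co2$x__i2)
  expect_equal(unname(fit2$coefficients), unname(oracle))
  expect_equal(fit2$n_used, 3L)
  # predictions equal the hand linear combination, for all rows
  newco <- tibble::tibble(x__i1 = c(0, 3, 10), x__i2 = NA_real_)
  expect_equal(predict_calibrated(fit2, newco),
               oracle[1] + oracle[2] * newco$x__i1)
})

test_that("first-stage slope estimates the reliability under classical error", {
  cfg <- one_var_config(n = 50000, reliability = 0.5, repeat_fraction = 1, seed = 51)
  co <- simulate_cohort(cfg)
  fit <- fit_first_stage(co, "x")
  expect_lt(abs(fit$coefficients[["x__i1"]] - 0.5), 0.01)
})

test_that("rank deficiency and missing repeats raise informative errors", {
  co <- tibble::tibble(x__i1 = c(1, 2, 3, 4), x__i2 = c(1, 2, 3, 4),
                       z__i1 = c(2, 4, 6, 8), z__i2 = c(2, 4, 6, 8),
                       y = 0)
  expect_error(fit_first_stage(co, "x", covariables = "z"),
               class = "undilute_rank_deficient")
  roles <- covariable_roles("x", confounders = "w", error_prone = c("x", "w"))
  co$w <- 1:4   # no w__i2 column
  expect_error(calibrate_cohort(co, roles), "no repeat measures")
  expect_error(fit_first_stage(tibble::tibble(x__i1 = 1:2, x__i2 = 1:2), "x"),
               "too few")
})

test_that("calibrated predictions shrink toward the mean", {
  cfg <- one_var_config(n = 5000, reliability = 0.5, repeat_fraction = 0.3, seed = 52)
  co <- simulate_cohort(cfg)
  fit <- fit_first_stage(co, "x")
  pred <- predict_calibrated(fit, co)
  expect_lt(var(pred), var(co$x__i1))
})

test_that("calibrate_cohort reduces to fit + predict and leaves the rest alone", {
  vars <- sim_variables(c("x", "w"), reliability = c(0.5, 0.9),
                        role = c("exposure", "confounder"), beta = c(1, 0.5))
  cfg <- sim_config(3000, vars, repeat_fraction = 0.3,
                    true_correlation = matrix(c(1, 0.3, 0.3, 1), 2),
                    outcome = sim_outcome("linear"), seed = 53)
  co <- simulate_cohort(cfg)
  roles_x <- covariable_roles("x", confounders = "w")
  cal <- calibrate_cohort(co, roles_x)
  manual <- predict_calibrated(fit_first_stage(co, "x", covariables = "w"), co)
  expect_equal(cal$x__i1, manual)
  expect_identical(cal$w__i1, co$w__i1)  # error-free covariable untouched
  expect_identical(cal$x__i2, co$x__i2)
  # no error-prone covariables: table unchanged
  roles_none <- covariable_roles("x", confounders = "w", error_prone = character())
  expect_identical(
    as.data.frame(calibrate_cohort(co, roles_none)[names(co)]),
    as.data.frame(co[names(co)]))
  # two error-prone covariables match sequential hand computation
  roles_both <- covariable_roles("x", confounders = "w", error_prone = c("x", "w"))
  cal2 <- calibrate_cohort(co, roles_both)
  ox_x <- normal_equations(cbind(1, co$x__i1, co$w__i1)[!is.na(co$x__i2), ],
                           co$x__i2[!is.na(co$x__i2)])
  ox_w <- normal_equations(cbind(1, co$w__i1, co$x__i1)[!is.na(co$w__i2), ],
                           co$w__i2[!is.na(co$w__i2)])
  expect_equal(cal2$x__i1, drop(cbind(1, co$x__i1, co$w__i1) %*% ox_x))
  expect_equal(cal2$w__i1, drop(cbind(1, co$w__i1, co$x__i1) %*% ox_w))
})

test_that("with perfect reliability the second stage equals the uncorrected fit", {
  cfg <- one_var_config(n = 2000, reliability = 1, repeat_fraction = 0.3, seed = 54)
  co <- simulate_cohort(cfg)
  roles <- covariable_roles("x")
  raw <- fit_second_stage(co, roles, "linear")
  cal <- fit_second_stage(calibrate_cohort(co, roles), roles, "linear")
  expect_equal(cal$estimates$estimate, raw$estimates$estimate, tolerance = 1e-10)
})

test_that("calibration undoes attenuation in linear and Cox models", {
  cfg <- one_var_config(n = 20000, reliability = 0.5, beta = 1,
                        repeat_fraction = 0.2, seed = 55)
  co <- simulate_cohort(cfg)
  roles <- covariable_roles("x")
  raw <- fit_second_stage(co, roles, "linear")$estimates$estimate
  cal <- fit_second_stage(calibrate_cohort(co, roles), roles, "linear")$estimates$estimate
  expect_lt(abs(raw - 0.5), 0.03)
  expect_lt(abs(cal - 1), 0.05)
  cfgc <- one_var_config(n = 20000, reliability = 0.5, beta = 0.3, family = "cox",
                         repeat_fraction = 0.2, target_event_fraction = 0.3,
                         seed = 56)
  coc <- simulate_cohort(cfgc)
  calc <- fit_second_stage(calibrate_cohort(coc, roles), roles, "cox")$estimates$estimate
  expect_lt(abs(calc - 0.3), 0.05)
})

test_that("bootstrap engine agrees with the public calibration path", {
  vars <- sim_variables(c("x", "w"), reliability = c(0.5, 0.8),
                        role = c("exposure", "confounder"), beta = c(0.4, 0.2))
  cfg <- sim_config(3000, vars, repeat_fraction = 0.3,
                    categorical = list(sim_categorical("g", c("a", "b", "c"),
                                                       c(0.5, 0.3, 0.2),
                                                       c(0, 0.2, 0.4))),
                    outcome = sim_outcome("cox", target_event_fraction = 0.3),
                    seed = 57)
  co <- simulate_cohort(cfg)
  roles <- covariable_roles("x", confounders = c("w", "g"),
                            error_prone = c("x", "w"), categorical = "g")
  boot <- bootstrap_calibration(co, roles, "cox", reps = 10, seed = 1)
  pub <- fit_second_stage(calibrate_cohort(co, roles), roles, "cox")
  engine_exp <- boot$estimates$estimate[boot$estimates$term == "x__i1"]
  public_exp <- pub$estimates$estimate[pub$estimates$term == "x__i1"]
  expect_equal(engine_exp, public_exp, tolerance = 1e-6)
})

test_that("whole-process bootstrap is seeded, stable and shrinks like sqrt(n)", {
  roles <- covariable_roles("x")
  make <- function(n, seed) simulate_cohort(one_var_config(
    n = n, reliability = 0.5, beta = 1, repeat_fraction = 0.2, seed = seed))
  co <- make(2000, 58)
  b1 <- bootstrap_calibration(co, roles, "linear", reps = 300, seed = 7)
  b2 <- bootstrap_calibration(co, roles, "linear", reps = 300, seed = 7)
  expect_identical(b1$estimates, b2$estimates)
  est <- b1$estimates[b1$estimates$term == "x__i1", ]
  expect_true(est$conf.low <= est$estimate && est$estimate <= est$conf.high)
  b3 <- bootstrap_calibration(co, roles, "linear", reps = 300, seed = 8)
  est3 <- b3$estimates[b3$estimates$term == "x__i1", ]
  width <- est$conf.high - est$conf.low
  expect_lt(abs(est3$conf.low - est$conf.low), width)
  co_big <- make(8000, 59)
  b4 <- bootstrap_calibration(co_big, roles, "linear", reps = 300, seed = 7)
  est4 <- b4$estimates[b4$estimates$term == "x__i1", ]
  ratio <- width / (est4$conf.high - est4$conf.low)
  expect_gt(ratio, 2 * 0.7)
  expect_lt(ratio, 2 * 1.3)
})

test_that("replicates without a usable repeat subsample are skipped or fatal", {
  co <- simulate_cohort(one_var_config(n = 400, repeat_fraction = 0.005, seed = 60))
  expect_identical(sum(!is.na(co$x__i2)), 2L)
  expect_error(
    bootstrap_calibration(co, covariable_roles("x"), "linear", reps = 20, seed = 1),
    "calibration failed|unusable")
})
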