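toy <- paired_measures(c(1, 3, 5, 7), c(2, 4, 6, 8))

test_that("two-way decomposition matches the hand and brute-force oracles", {
  d <- anova_decompose(toy)
  expect_equal(d$msr, 40 / 3)
  expect_equal(d$msc, 2)
  expect_equal(d$mse, 0)
  # sum-of-squares identity on the balanced layout
  x <- c(toy$o1, toy$o2)
  expect_equal((d$n - 1) * d$msr + d$msc + (d$n - 1) * d$mse,
               sum((x - mean(x))^2))
  # random 10x2 table against explicit cell sums
  set.seed(31)
  o1 <- rnorm(10); o2 <- rnorm(10)
  got <- anova_decompose(paired_measures(o1, o2))
  want <- brute_force_anova(o1, o2)
  expect_equal(got$msr, want$msr)
  expect_equal(got$msc, want$msc)
  expect_equal(got$mse, want$mse)
  expect_error(anova_decompose(paired_measures(1, 2)), "2 complete pairs")
})

test_that("ICC conventions give the closed-form fractions on the toy table", {
  expect_equal(icc_estimate(toy, "consistency")$icc, 1)
  expect_equal(icc_estimate(toy, "agreement")$icc, 40 / 43)
  ident <- paired_measures(c(1, 2, 3), c(1, 2, 3))
  expect_equal(icc_estimate(ident, "consistency")$icc, 1)
  expect_equal(icc_estimate(ident, "agreement")$icc, 1)
})

test_that("ICC recovers the simulated reliability and its CI brackets it", {
  cfg <- one_var_config(n = 5000, reliability = 0.6, repeat_fraction = 1, seed = 21)
  co <- simulate_cohort(cfg)
  pm <- extract_pairs(co, "x")
  ic <- icc_estimate(pm)
  expect_lt(abs(ic$icc - 0.6), 0.03)
  expect_true(ic$conf.low < ic$icc && ic$icc < ic$conf.high)
  # with a systematic shift, absolute agreement < consistency
  cfg_s <- sim_config(5000, sim_variables("x", reliability = 0.8, shift = 0.8),
                      repeat_fraction = 1, seed = 22)
  co_s <- simulate_cohort(cfg_s)
  pm_s <- extract_pairs(co_s, "x")
  expect_lt(icc_estimate(pm_s, "agreement")$icc,
            icc_estimate(pm_s, "consistency")$icc)
})

test_that("accuracy coefficient matches its closed forms and invariances", {
  expect_equal(accuracy_coefficient(toy), 10 / 11)
  # doubled spread, equal means: Cb = 2*2/(1 + 4) = 0.8
  dbl <- paired_measures(rep(c(-1, 1), 10), rep(c(-2, 2), 10))
  expect_equal(accuracy_coefficient(dbl), 0.8)
  ident <- paired_measures(c(1, 5, 9), c(1, 5, 9))
  expect_equal(accuracy_coefficient(ident), 1)
  # symmetric in occasions, invariant to common rescaling
  swapped <- paired_measures(toy$o2, toy$o1)
  expect_equal(accuracy_coefficient(swapped), accuracy_coefficient(toy))
  scaled <- paired_measures(3 * toy$o1, 3 * toy$o2)
  expect_equal(accuracy_coefficient(scaled), accuracy_coefficient(toy))
  expect_error(accuracy_coefficient(paired_measures(c(1, 1), c(1, 2))),
               "zero variance")
})

test_that("bootstrap ICC variance is calibrated and shrinks with n", {
  ident <- paired_measures(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(as.numeric(var_icc(ident, B = 100, seed = 1)), 0)
  expect_error(var_icc(toy, B = 1), ">= 2")
  # against the empirical variance of the estimator across 500 datasets
  sim_icc <- function(seed, n) {
    cfg <- one_var_config(n = n, reliability = 0.6, repeat_fraction = 1, seed = seed)
    co <- simulate_cohort(cfg)
    icc_estimate(extract_pairs(co, "x"))$icc
  }
  emp <- var(vapply(1:500, sim_icc, numeric(1), n = 500))
  cfg <- one_var_config(n = 500, reliability = 0.6, repeat_fraction = 1, seed = 777)
  boot <- as.numeric(var_icc(extract_pairs(simulate_cohort(cfg), "x"),
                             B = 500, seed = 5))
  expect_lt(boot, 2 * emp)
  expect_gt(boot, emp / 2)
  cfg_big <- one_var_config(n = 5000, reliability = 0.6, repeat_fraction = 1, seed = 778)
  boot_big <- as.numeric(var_icc(extract_pairs(simulate_cohort(cfg_big), "x"),
                                 B = 500, seed = 5))
  expect_lt(boot_big, boot)
  # deterministic under seed
  pm <- extract_pairs(simulate_cohort(cfg), "x")
  expect_identical(var_icc(pm, B = 200, seed = 9), var_icc(pm, B = 200, seed = 9))
})

test_that("correction-factor statistics obey the delta identity", {
  rel <- reliability_statistics(0.5, 0.0001)
  expect_equal(rel$lambda, 2)
  expect_equal(rel$var_inv_lambda, 0.0001)
  expect_equal(rel$var_lambda, 0.0001 / 0.5^4)
  expect_equal(rel$var_inv_lambda, rel$var_lambda / rel$lambda^4)
  expect_error(reliability_statistics(-0.1, 0.01),
               class = "undilute_icc_nonpositive")
})

test_that("published correction-factor variance pairs satisfy the delta identity", {
  # catalogue rows: lambda and var(lambda) in, var(1/lambda) out at 6 dp
  rows <- tibble::tribble(
    ~lambda, ~var_lambda, ~var_inv_lambda,
    1.9356, 0.000410, 0.000029,   # red cell distribution width
    3.4987, 0.007635, 0.000051,   # C-reactive protein
    1.8091, 0.000335, 0.000031,   # 25-hydroxyvitamin D
    1.0794, 0.000001, 0.000001,   # body mass index
    1.1745, 0.000030, 0.000016    # smoking pack-years
  )
  for (i in seq_len(nrow(rows))) {
    implied_var_icc <- rows$var_lambda[i] / rows$lambda[i]^4
    rel <- reliability_statistics(1 / rows$lambda[i], implied_var_icc)
    expect_equal(round(rel$var_inv_lambda, 6), rows$var_inv_lambda[i])
    expect_equal(rel$var_lambda, rows$var_lambda[i], tolerance = 1e-6)
  }
})

test_that("agreement() bundles the statistics consistently", {
  cfg <- one_var_config(n = 2000, reliability = 0.7, repeat_fraction = 1, seed = 23)
  pm <- extract_pairs(simulate_cohort(cfg), "x")
  a <- agreement(pm, boot = 200, seed = 4)
  expect_equal(a$lambda * a$icc, 1)
  expect_equal(a$var_inv_lambda, a$var_icc)
  expect_equal(a$var_lambda, a$var_inv_lambda * a$lambda^4, tolerance = 1e-10)
  td <- tidy(a)
  expect_equal(td$estimate[td$term == "icc"], a$icc)
  expect_equal(nrow(glance(a)), 1L)
})

test_that("category summaries use interpolated quartiles", {
  cat1 <- tibble::tibble(icc = 0.7, category = "a")
  s1 <- summarize_categories(cat1)
  expect_equal(c(s1$median, s1$q1, s1$q3), c(0.7, 0.7, 0.7))
  s2 <- summarize_categories(tibble::tibble(icc = c(0.1, 0.2, 0.3), category = "a"))
  expect_equal(s2$median, 0.2)
  # type-7 closed form on {0.1, 0.2, 0.3, 0.4}: h = 1.75 and 3.25
  s3 <- summarize_categories(tibble::tibble(icc = c(0.1, 0.2, 0.3, 0.4), category = "a"))
  expect_equal(s3$q1, 0.175)
  expect_equal(s3$q3, 0.325)
  cat_f <- tibble::tibble(icc = c(0.5, 0.6),
                          category = factor(c("a", "a"), levels = c("a", "b")))
  expect_warning(summarize_categories(cat_f), "empty")
})
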