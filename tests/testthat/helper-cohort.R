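# small reusable simulation setups for the test suite

one_var_config <- function(n = 2000, reliability = 0.5, beta = 1, sd = 1,
                           mean = 0, shift = 0, repeat_fraction = 0.1,
                           family = "linear", seed = 1L, ...) {
  sim_config(
    n = n,
    variables = sim_variables("x", mean = mean, sd = sd,
                              reliability = reliability, shift = shift,
                              role = "exposure", beta = beta),
    repeat_fraction = repeat_fraction,
    outcome = if (family == "linear") sim_outcome("linear", residual_sd = 1)
              else sim_outcome("cox", ...),
    seed = seed
  )
}

# brute-force two-way ANOVA mean squares by explicit sums over all cells
brute_force_anova <- function(o1, o2) {
  x <- cbind(o1, o2)
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

# OLS coefficients via explicit normal equations (independent oracle)
normal_equations <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))
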