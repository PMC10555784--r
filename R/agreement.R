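#' Paired two-occasion measurements
#'
#' @param o1,o2 Numeric vectors of the occasion-1 and occasion-2 values.
#' @param id Optional participant ids.
#' @return A tibble of complete pairs (class `"paired_measures"`).
#' @export
#' @examples
#' paired_measures(c(1, 3, 5, 7), c(2, 4, 6, 8))
paired_measures <- function(o1, o2, id = NULL) {
  if (length(o1) != length(o2)) abort("`o1` and `o2` must have equal length.")
  id <- id %||% seq_along(o1)
  keep <- is.finite(o1) & is.finite(o2)
  out <- tibble(id = id[keep], o1 = as.numeric(o1[keep]), o2 = as.numeric(o2[keep]))
  if (nrow(out) < 2) abort("need at least 2 complete pairs.")
  class(out) <- c("paired_measures", class(out))
  out
}

#' Extract the complete repeat pairs of one variable from a cohort
#'
#' @param cohort Wide cohort tibble with `<var>__i1` / `<var>__i2` columns.
#' @param var Variable name (without suffix).
#' @return A [paired_measures()] tibble.
#' @export
extract_pairs <- function(cohort, var) {
  c1 <- occ1(var); c2 <- occ2(var)
  if (!all(c(c1, c2) %in% names(cohort))) {
    abort(sprintf("cohort has no occasion columns for variable '%s'.", var))
  }
  paired_measures(cohort[[c1]], cohort[[c2]],
                  id = cohort[["id"]] %||% seq_len(nrow(cohort)))
}

#' Two-way ANOVA decomposition of a balanced subjects-by-occasions table
#'
#' Exact mean squares of the balanced two-way layout (n subjects, k = 2
#' occasions, one observation per cell): `msr` between subjects, `msc`
#' between occasions, `mse` residual. For k = 2 these reduce to
#' msr = var(o1 + o2)/2, msc = n * mean(o1 - o2)^2 / 2 and
#' mse = var(o1 - o2)/2 (sample variances), which is exact algebra, not an
#' approximation.
#'
#' @param paired A [paired_measures()] tibble (or any data frame with columns
#'   `o1`, `o2`).
#' @return List of class `"anova_twoway"`: `msr`, `msc`, `mse`, `n`, `k`.
#' @export
#' @examples
#' anova_decompose(paired_measures(c(1, 3, 5, 7), c(2, 4, 6, 8)))
anova_decompose <- function(paired) {
  o1 <- paired$o1; o2 <- paired$o2
  n <- length(o1)
  if (n < 2) abort("need at least 2 pairs for the ANOVA decomposition.")
  s <- o1 + o2
  d <- o1 - o2
  structure(
    list(msr = stats::var(s) / 2,
         msc = n * mean(d)^2 / 2,
         mse = stats::var(d) / 2,
         n = n, k = 2L),
    class = "anova_twoway"
  )
}

#' Intraclass correlation coefficient from a two-way decomposition
#'
#' Single-measurement ICC of a two-way mixed-effects model. The
#' `"agreement"` convention (absolute agreement; default, the recommended
#' form for test-retest data) is
#' (msr - mse) / (msr + (k-1) mse + (k/n)(msc - mse)); the `"consistency"`
#' convention drops the occasion term: (msr - mse) / (msr + (k-1) mse).
#' Confidence intervals use the standard F-based closed forms
#' (Satterthwaite-approximated denominator degrees of freedom for the
#' agreement convention).
#'
#' @param decomp An [anova_decompose()] result, or a [paired_measures()]
#'   tibble (decomposed on the fly).
#' @param convention `"agreement"` (absolute agreement) or `"consistency"`.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `icc`, `conf.low`, `conf.high`, `convention`, `level`.
#' @export
#' @examples
#' icc_estimate(paired_measures(c(1, 3, 5, 7), c(2, 4, 6, 8)), "consistency")
icc_estimate <- function(decomp, convention = c("agreement", "consistency"),
                         level = 0.95) {
  convention <- match.arg(convention)
  if (inherits(decomp, "paired_measures") || is.data.frame(decomp)) {
    decomp <- anova_decompose(decomp)
  }
  stopifnot(inherits(decomp, "anova_twoway"))
  msr <- decomp$msr; msc <- decomp$msc; mse <- decomp$mse
  n <- decomp$n; k <- decomp$k
  alpha <- 1 - level

  if (convention == "consistency") {
    den <- msr + (k - 1) * mse
    if (den <= 0) abort("degenerate table: zero denominator for the ICC.")
    icc <- (msr - mse) / den
    if (mse == 0) {
      lo <- hi <- icc
    } else {
      fobs <- msr / mse
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  } else {
    den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    if (den <= 0) abort("degenerate table: zero denominator for the ICC.")
    icc <- (msr - mse) / den
    if (mse == 0 && msc == 0) {
      lo <- hi <- icc
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      if (!is.finite(a) || !is.finite(b)) {  # icc == 1 with msc > 0
        lo <- hi <- icc
      } else {
        v <- (a * msc + b * mse)^2 /
          ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
        fl <- stats::qf(1 - alpha / 2, n - 1, v)
        fu <- stats::qf(1 - alpha / 2, v, n - 1)
        lo <- n * (msr - fl * mse) /
          (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
        hi <- n * (fu * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fu * msr)
      }
    }
  }
  tibble(icc = icc, conf.low = lo, conf.high = hi,
         convention = convention, level = level)
}

#' Lin's accuracy coefficient
#'
#' The bias-correction component Cb of Lin's concordance correlation:
#' Cb = 2 s1 s2 / (s1^2 + s2^2 + (m1 - m2)^2), a measure of how close the
#' line of best fit between the two occasions is to the 45-degree line
#' through the origin. Always in (0, 1]; values near 1 indicate negligible
#' systematic (location or scale) difference between occasions.
#'
#' @param paired A [paired_measures()] tibble.
#' @param moments `"population"` (1/n, Lin's original definition; default) or
#'   `"sample"` (1/(n-1)).
#' @return The accuracy coefficient (single number).
#' @export
#' @examples
#' accuracy_coefficient(paired_measures(c(1, 3, 5, 7), c(2, 4, 6, 8)))
accuracy_coefficient <- function(paired, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  o1 <- paired$o1; o2 <- paired$o2
  s1 <- if (moments == "population") sd_pop(o1) else stats::sd(o1)
  s2 <- if (moments == "population") sd_pop(o2) else stats::sd(o2)
  if (s1 == 0 || s2 == 0) abort("zero variance in one occasion: Cb undefined.")
  2 * s1 * s2 / (s1^2 + s2^2 + (mean(o1) - mean(o2))^2)
}

# vectorised ICC over B bootstrap resamples, using the k = 2 closed forms
.icc_boot_stats <- function(o1, o2, B, convention, chunk = 200L) {
  n <- length(o1)
  s <- o1 + o2
  d <- o1 - o2
  est <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    S <- matrix(s[idx], nrow = n)
    D <- matrix(d[idx], nrow = n)
    vs <- (colMeans(S^2) - colMeans(S)^2) * n / (n - 1)
    vd <- (colMeans(D^2) - colMeans(D)^2) * n / (n - 1)
    msr <- vs / 2
    mse <- vd / 2
    msc <- n * colMeans(D)^2 / 2
    est[done + seq_len(b)] <- if (convention == "consistency") {
      (msr - mse) / (msr + mse)
    } else {
      (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
    }
    done <- done + b
  }
  est
}

#' Bootstrap sampling variance of the ICC estimate
#'
#' Nonparametric bootstrap over participants: pairs are resampled with
#' replacement B times, the ICC recomputed for each resample, and the
#' variance of the resampled estimates returned. Deterministic under `seed`.
#'
#' @param paired A [paired_measures()] tibble.
#' @param B Number of bootstrap resamples (default 1000; must be >= 2).
#' @param seed Integer seed.
#' @param convention Passed to [icc_estimate()].
#' @return The variance estimate, with the resampled ICCs in attribute
#'   `"estimates"`.
#' @export
var_icc <- function(paired, B = 1000, seed = 1L,
                    convention = c("agreement", "consistency")) {
  convention <- match.arg(convention)
  if (B < 2) abort("`B` must be >= 2.")
  est <- local_seed(seed, .icc_boot_stats(paired$o1, paired$o2, B, convention))
  # a resample may degenerate (every drawn pair identical): ICC undefined there
  out <- stats::var(est[is.finite(est)])
  attr(out, "estimates") <- est
  out
}

#' Correction factor and its derived variances
#'
#' The regression dilution correction factor is the reciprocal of the ICC,
#' lambda = 1 / ICC. Given the sampling variance of the ICC (= var(1/lambda)),
#' the first-order delta method gives var(lambda) = var(ICC) / ICC^4, so the
#' pair satisfies var(1/lambda) = var(lambda) / lambda^4.
#'
#' @param icc ICC estimate (> 0; no correction factor exists otherwise).
#' @param var_icc Sampling variance of the ICC estimate.
#' @return Tibble with `lambda`, `var_lambda`, `var_inv_lambda`.
#' @export
#' @examples
#' reliability_statistics(0.52, 0.000029)
reliability_statistics <- function(icc, var_icc = NA_real_) {
  check_number(icc, "icc")
  if (icc <= 0) {
    abort("correction factor undefined for icc <= 0.",
          class = "undilute_icc_nonpositive")
  }
  tibble(lambda = 1 / icc,
         var_lambda = var_icc / icc^4,
         var_inv_lambda = var_icc)
}

#' Full agreement analysis of one repeat-measured variable
#'
#' Combines the two-way ANOVA ICC (with confidence interval), Lin's accuracy
#' coefficient, the per-occasion moments, and the correction-factor
#' statistics (bootstrap variance of the ICC and its delta-method
#' counterparts) into one result object with [generics::tidy()] /
#' [generics::glance()] methods.
#'
#' @param paired A [paired_measures()] tibble.
#' @param convention ICC convention, see [icc_estimate()].
#' @param level Confidence level.
#' @param boot Bootstrap resamples for [var_icc()]; set to 0 to skip the
#'   variance computation.
#' @param seed Seed for the bootstrap.
#' @return An object of class `"agreement_result"`.
#' @export
#' @examples
#' pm <- paired_measures(rnorm(200), rnorm(200))
#' agreement(pm, boot = 50)
agreement <- function(paired, convention = c("agreement", "consistency"),
                      level = 0.95, boot = 1000, seed = 1L) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(paired), all(c("o1", "o2") %in% names(paired)))
  ic <- icc_estimate(paired, convention, level)
  m1 <- mean(paired$o1); m2 <- mean(paired$o2)
  s1 <- sd_pop(paired$o1); s2 <- sd_pop(paired$o2)
  vic <- if (boot >= 2) as.numeric(var_icc(paired, B = boot, seed = seed,
                                           convention = convention))
         else NA_real_
  rel <- if (ic$icc > 0) reliability_statistics(ic$icc, vic) else
    tibble(lambda = NA_real_, var_lambda = NA_real_, var_inv_lambda = vic)
  structure(
    list(n_pairs = nrow(paired),
         icc = ic$icc, conf.low = ic$conf.low, conf.high = ic$conf.high,
         convention = convention, level = level,
         accuracy = accuracy_coefficient(paired),
         mu1 = m1, mu2 = m2, sigma1 = s1, sigma2 = s2,
         u = (m1 - m2) / sqrt(s1 * s2), v = s1 / s2,
         lambda = rel$lambda, var_icc = vic,
         var_lambda = rel$var_lambda, var_inv_lambda = rel$var_inv_lambda,
         icc_flag = if (ic$icc <= 0) "nonpositive_icc" else NA_character_),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result>  n = %d pairs\n", x$n_pairs))
  cat(sprintf("  ICC (%s) = %.4f  [%.4f, %.4f]  (%.0f%%)\n",
              x$convention, x$icc, x$conf.low, x$conf.high, 100 * x$level))
  cat(sprintf("  accuracy coefficient Cb = %.4f\n", x$accuracy))
  if (is.finite(x$lambda)) {
    cat(sprintf("  correction factor lambda = %.4f", x$lambda))
    if (is.finite(x$var_lambda)) {
      cat(sprintf("   var(lambda) = %.6f   var(1/lambda) = %.6f",
                  x$var_lambda, x$var_inv_lambda))
    }
    cat("\n")
  }
  if (!is.na(x$icc_flag)) cat("  flag:", x$icc_flag, "\n")
  invisible(x)
}

#' Median and interquartile range of ICCs by variable category
#'
#' @param catalogue Tibble with at least columns `icc` and a category column.
#' @param category Name of the category column (default `"category"`).
#' @return Tibble with `category`, `n`, `median`, `q1`, `q3`. Quantiles use
#'   linear interpolation between order statistics
#'   ([stats::quantile()] type 7). Empty categories are dropped with a
#'   warning.
#' @export
summarize_categories <- function(catalogue, category = "category") {
  stopifnot("icc" %in% names(catalogue), category %in% names(catalogue))
  cat_f <- catalogue[[category]]
  keep <- !is.na(catalogue$icc)
  if (is.factor(cat_f)) {
    empty <- setdiff(levels(cat_f), unique(as.character(cat_f[keep])))
    if (length(empty)) {
      warn(paste("omitting empty categories:", paste(empty, collapse = ", ")))
    }
  }
  catalogue[keep, ] |>
    dplyr::group_by(category = as.character(cat_f[keep])) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$icc),
      q1 = stats::quantile(.data$icc, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$icc, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
}
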