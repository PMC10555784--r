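#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_errorbar
#'   geom_errorbarh geom_vline geom_hline labs theme_minimal geom_histogram
#' @export
ggplot2::autoplot

#' Scatter plot of paired repeat measurements
#'
#' Occasion 2 against occasion 1 with the 45-degree line of perfect
#' agreement; systematic shifts show up as departures from the line.
#'
#' @param object A [paired_measures()] tibble.
#' @param alpha Point transparency.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.paired_measures <- function(object, alpha = 0.4, ...) {
  ggplot(object, aes(x = .data$o1, y = .data$o2)) +
    geom_point(alpha = alpha) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    labs(x = "occasion 1", y = "occasion 2") +
    theme_minimal()
}

#' Catalogue plot of ICCs with confidence intervals
#'
#' @param object An [run_agreement_scan()] result.
#' @param ... Unused.
#' @return A ggplot (one row per variable, coloured by category if present).
#' @export
autoplot.agreement_scan <- function(object, ...) {
  cat_df <- object$catalogue
  p <- ggplot(cat_df, aes(x = .data$icc, y = stats::reorder(.data$variable, .data$icc))) +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.2, colour = "grey55") +
    labs(x = "intraclass correlation coefficient", y = NULL) +
    theme_minimal()
  if ("category" %in% names(cat_df)) {
    p <- p + geom_point(aes(colour = .data$category))
  } else {
    p <- p + geom_point()
  }
  p
}

#' Forest plot of the four-model comparison
#'
#' @param object A [run_corrected_analysis()] result.
#' @param ... Unused.
#' @return A ggplot with the null line at 1 (ratio scale) or 0.
#' @export
autoplot.rdb_comparison <- function(object, ...) {
  null_at <- if (identical(attr(object, "scale"), "ratio")) 1 else 0
  ggplot(object, aes(x = .data$estimate,
                     y = factor(.data$label, levels = rev(.data$label)))) +
    geom_vline(xintercept = null_at, linetype = 2, colour = "grey40") +
    geom_errorbarh(aes(xmin = .data$conf.low, xmax = .data$conf.high),
                   height = 0.15) +
    geom_point(size = 2) +
    labs(x = if (null_at == 1) "ratio estimate (95% CI)"
             else "coefficient (95% CI)", y = NULL) +
    theme_minimal()
}

#' Histogram of bootstrap replicate estimates
#'
#' @param object A [bootstrap_calibration()] result.
#' @param term Coefficient to plot (default: the exposure term).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot with the percentile interval marked.
#' @export
autoplot.rc_boot <- function(object, term = NULL, bins = 40, ...) {
  term <- term %||% object$exposure_term
  est <- dplyr::filter(object$estimates, .data$term == !!term)
  df <- tibble(value = object$replicates[[term]])
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = c(est$conf.low, est$estimate, est$conf.high),
               linetype = c(2, 1, 2)) +
    labs(x = paste("replicate estimate:", term), y = "count") +
    theme_minimal()
}
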