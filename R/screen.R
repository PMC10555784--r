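#' Resolve threshold-coded string values to numerics
#'
#' Field catalogues often record detection-limit or capped values as strings
#' such as `"<=1"` or `">90"`. The default `"boundary"` policy substitutes the
#' stated boundary (so `"<=1"` becomes 1); the `"missing"` policy drops them.
#' Plain numeric strings pass through; anything unparseable becomes missing.
#' Both the unicode relations (≤, ≥) and their ASCII spellings
#' (`<=`, `>=`, `<`, `>`) are recognised.
#'
#' @param x Character or numeric vector.
#' @param policy `"boundary"` (default) or `"missing"`.
#' @return Numeric vector with attribute `"n_coerced"` counting resolved codes.
#' @export
#' @examples
#' coerce_threshold_codes(c("<=1", "5.2", "", ">=29"))
coerce_threshold_codes <- function(x, policy = c("boundary", "missing")) {
  policy <- match.arg(policy)
  if (is.numeric(x)) {
    out <- as.numeric(x)
    attr(out, "n_coerced") <- 0L
    return(out)
  }
  x <- trimws(as.character(x))
  plain <- suppressWarnings(as.numeric(x))
  coded <- is.na(plain) & grepl("^(≤|≥|<=|>=|<|>)\\s*-?[0-9.]+$", x)
  bound <- suppressWarnings(as.numeric(sub("^(≤|≥|<=|>=|<|>)\\s*", "", x)))
  out <- plain
  if (policy == "boundary") out[coded] <- bound[coded]
  attr(out, "n_coerced") <- sum(coded)
  out
}

#' Collapse multiple readings within one visit to a single value
#'
#' @param readings Numeric vector of readings taken at one visit.
#' @param policy `"mean"` (default; arithmetic mean of valid readings) or
#'   `"first"` (first non-missing reading).
#' @return A single value, or `NA` if no reading is valid.
#' @export
#' @examples
#' collapse_visit_readings(c(80, 84))
collapse_visit_readings <- function(readings, policy = c("mean", "first")) {
  policy <- match.arg(policy)
  readings <- readings[is.finite(readings)]
  if (length(readings) == 0) return(NA_real_)
  if (policy == "mean") mean(readings) else readings[[1]]
}

#' Classify a variable as continuous or not
#'
#' Real-valued variables are continuous; integer-valued variables are treated
#' as continuous only when they take more than 20 distinct values.
#'
#' @param values Numeric vector (after threshold-code coercion), missing
#'   allowed.
#' @return A list with `class` (`"continuous"`, `"continuous_integer"` or
#'   `"not_continuous"`) and `distinct_count`.
#' @export
classify_variable <- function(values) {
  values <- values[!is.na(values)]
  d <- length(unique(values))
  if (d == 0) return(list(class = "not_continuous", distinct_count = 0L))
  if (all(values == round(values))) {
    cls <- if (d > 20) "continuous_integer" else "not_continuous"
  } else {
    cls <- "continuous"
  }
  list(class = cls, distinct_count = as.integer(d))
}

#' Apply the variable-eligibility rules
#'
#' One decision per variable, with exclusion reasons assigned in fixed
#' precedence: `no_repeat`, then `not_continuous`, then `too_many_ties`
#' (more than 20% of participants share one value; a share of exactly 0.20
#' passes), then `too_few_repeats` (fewer than 100 complete repeat pairs;
#' exactly 100 passes).
#'
#' @param meta Tibble with columns `variable`, `has_repeat` (logical),
#'   `class`, `distinct_count`, `max_value_share`, `n_repeat_pairs`.
#' @return Tibble of screening decisions (`verdict`, `reason` plus the input
#'   counts).
#' @export
apply_eligibility <- function(meta) {
  stopifnot(all(c("variable", "has_repeat", "class", "distinct_count",
                  "max_value_share", "n_repeat_pairs") %in% names(meta)))
  reason <- dplyr::case_when(
    !meta$has_repeat ~ "no_repeat",
    meta$class == "not_continuous" ~ "not_continuous",
    meta$max_value_share > 0.20 ~ "too_many_ties",
    meta$n_repeat_pairs < 100 ~ "too_few_repeats",
    TRUE ~ "ok"
  )
  dplyr::mutate(as_tibble(meta),
                reason = reason,
                verdict = ifelse(reason == "ok", "include", "exclude"))
}

#' Screen a wide two-occasion table for eligible variables
#'
#' Detects variables by their `<var>__i1` columns, resolves threshold codes,
#' and applies the eligibility rules of [apply_eligibility()]. The tie share
#' is computed on occasion-1 non-missing values (the analysis measure).
#'
#' @param data Wide tibble/data frame with `<var>__i1` (and optionally
#'   `<var>__i2`) columns.
#' @param threshold_policy Passed to [coerce_threshold_codes()].
#' @return A tibble with one decision row per variable
#'   (class `"screening_decisions"`); per-reason counts via [screening_summary()].
#' @export
#' @examples
#' screen_variables(generate_showcase_table(seed = 1))
screen_variables <- function(data, threshold_policy = c("boundary", "missing")) {
  threshold_policy <- match.arg(threshold_policy)
  vars <- sub("__i1$", "", grep("__i1$", names(data), value = TRUE))
  if (length(vars) == 0) {
    out <- tibble(variable = character(), has_repeat = logical(),
                  class = character(), distinct_count = integer(),
                  max_value_share = double(), n_repeat_pairs = integer(),
                  reason = character(), verdict = character())
    class(out) <- c("screening_decisions", class(out))
    return(out)
  }
  meta <- purrr::map_dfr(vars, function(v) {
    x1 <- coerce_threshold_codes(data[[occ1(v)]], threshold_policy)
    has_i2 <- occ2(v) %in% names(data)
    x2 <- if (has_i2) coerce_threshold_codes(data[[occ2(v)]], threshold_policy)
          else rep(NA_real_, length(x1))
    cls <- classify_variable(x1)
    x1v <- x1[!is.na(x1)]
    share <- if (length(x1v)) max(tabulate(match(x1v, unique(x1v)))) / length(x1v) else 0
    tibble(variable = v,
           has_repeat = any(!is.na(x2)),
           class = cls$class,
           distinct_count = cls$distinct_count,
           max_value_share = share,
           n_repeat_pairs = sum(!is.na(x1) & !is.na(x2)))
  })
  out <- apply_eligibility(meta)
  class(out) <- c("screening_decisions", class(out))
  out
}

#' Summarise screening decisions by reason
#'
#' @param decisions Output of [screen_variables()].
#' @return Tibble of counts per reason; the counts partition the variable set.
#' @export
screening_summary <- function(decisions) {
  dplyr::count(as_tibble(decisions), .data$verdict, .data$reason, name = "n")
}
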