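#' Write a cohort to CSV with a JSON provenance sidecar
#'
#' One row per participant; occasion columns keep their `__i1`/`__i2`
#' suffixes; missing values are written as empty strings. When the cohort
#' carries a generating config (as cohorts from [simulate_cohort()] do), it
#' is written alongside as `<stem>_config.json`, including the seed.
#'
#' @param cohort Wide cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  config <- attr(cohort, "config")
  if (!is.null(config)) {
    sidecar <- sub("\\.csv$", "", path)
    cfg <- config
    cfg$true_correlation <- unclass(cfg$true_correlation)
    jsonlite::write_json(unclass(cfg), paste0(sidecar, "_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path (UTF-8, header row, empty string = missing).
#' @return A wide cohort tibble.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a simulation config from YAML
#'
#' The YAML mirrors the arguments of [sim_config()]: top-level `n`,
#' `repeat_fraction`, `seed`, a `variables` list (name, mean, sd,
#' reliability, shift, role, beta per entry), optional `true_correlation`
#' (row-major list of rows), optional `categorical` entries (name, levels,
#' probs, log_hazards) and an `outcome` block.
#'
#' @param path YAML file path.
#' @return A validated [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vars <- purrr::map_dfr(raw$variables, function(v) {
    sim_variables(v$name, v$mean %||% 0, v$sd %||% 1, v$reliability %||% 1,
                  v$shift %||% 0, v$role %||% "confounder", v$beta %||% 0)
  })
  corr <- if (!is.null(raw$true_correlation)) {
    do.call(rbind, lapply(raw$true_correlation, as.numeric))
  }
  cats <- purrr::map(raw$categorical %||% list(), function(cc) {
    sim_categorical(cc$name, cc$levels, cc$probs,
                    cc$log_hazards %||% rep(0, length(cc$levels)))
  })
  oc <- raw$outcome %||% list()
  outcome <- sim_outcome(oc$family %||% "cox",
                         oc$baseline_hazard %||% 0.02,
                         oc$horizon %||% 15,
                         oc$target_event_fraction,
                         oc$uniform_censor_max,
                         oc$residual_sd %||% 1)
  sim_config(n = raw$n, variables = vars,
             repeat_fraction = raw$repeat_fraction %||% 0.10,
             true_correlation = corr, categorical = cats,
             outcome = outcome, seed = raw$seed %||% 1L)
}
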