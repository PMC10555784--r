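#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

# occasion-suffixed column names used throughout the cohort layout
occ1 <- function(var) paste0(var, "__i1")
occ2 <- function(var) paste0(var, "__i2")

# population (1/n) variance and sd
var_pop <- function(x) mean((x - mean(x))^2)
sd_pop <- function(x) sqrt(var_pop(x))
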