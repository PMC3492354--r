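# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb user randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Percentage of k out of n, truncated (not rounded) to one decimal place,
# matching how consensus methylation/expression concordance rates are
# conventionally printed (5/13 -> 38.4, 10/136 -> 7.3).
truncate_pct <- function(k, n) {
  if (n == 0) return(NA_real_)
  floor(1000 * k / n + 1e-9) / 10
}

# Stop with a classed condition so callers can test/handle specific failures.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "methcall_error")))
}

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single fraction in [0, 1]", name),
          "methcall_config_error")
  }
  invisible(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a
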