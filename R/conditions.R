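# Classed error conditions so callers (and the CLI) can distinguish user
# errors from internal failures.

db_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "digibead_error")))
}

db_invalid <- function(msg) db_stop(msg, "digibead_invalid_parameter")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the prior
#' RNG state, so simulation functions are pure functions of their arguments
#' and never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    db_invalid(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    db_invalid(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  if (integer && x != round(x))
    db_invalid(sprintf("'%s' must be an integer, got %s", name, x))
  invisible(x)
}
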