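# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so simulation functions are deterministic without clobbering the
#' session seed.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stop_brustab <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_brustab("'%s' must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_brustab("'%s' must be > %g (got %g)", name, lower, x)
  }
  if (!strict_lower && x < lower) {
    stop_brustab("'%s' must be >= %g (got %g)", name, lower, x)
  }
  if (x > upper) stop_brustab("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

#' Geometric mean ignoring nothing; returns 0 if any element is 0
#' @noRd
geomean <- function(x) exp(mean(log(x)))
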