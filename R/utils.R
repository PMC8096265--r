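# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#'
#' All stochastic generators in the package route randomness through this so
#' that results are bit-reproducible for a given seed and the caller's RNG
#' stream is left untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# single positive count
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1) {
    stop(sprintf("`%s` must be a positive count", name), call. = FALSE)
  }
  invisible(TRUE)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Geometric mean
#' @param x positive numeric vector.
#' @return geometric mean of `x`.
#' @keywords internal
#' @noRd
geometric_mean <- function(x) exp(mean(log(x)))
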