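#' Logistic function
#'
#' Standard logistic \eqn{\sigma(x) = 1/(1+e^{-x})}, used by the induction
#' profile and the sigmoid/impulse kinetic models.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @keywords internal
logistic <- function(x) {
  # plogis is numerically stable for large |x|
  stats::plogis(x)
}

#' Derive a child seed from a base seed and a label
#'
#' Deterministically maps (seed, label) to a new 31-bit seed so that
#' independent stages of a pipeline can be given unrelated but reproducible
#' RNG streams.
#'
#' @param seed integer base seed.
#' @param label character scalar naming the stage.
#' @return a single integer in [0, 2^31 - 1].
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.integer(seed) %% 2147483647L
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647L
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores .Random.seed so library functions that seed the RNG do
#' not perturb the caller's stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
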