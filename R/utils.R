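#' Derive a deterministic sub-stream seed
#'
#' Generators draw each logical block of randomness (positions, intensities,
#' noise, ...) under its own seed derived from the single user-facing seed, so
#' enlarging one block never perturbs the draws of another.
#'
#' @param seed integer master seed.
#' @param stream integer index of the sub-stream (1, 2, ...).
#' @return an integer seed strictly below 2^31.
#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # multiplicative congruential step (Park-Miller modulus), pure integer-safe
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  for (i in seq_len(stream)) {
    s <- (s * 48271) %% 2147483647
  }
  as.integer(s)
}

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so package generators behave as
#' pure functions of their parameters.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
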