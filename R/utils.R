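#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so seeded operations do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed
#'
#' Deterministic integer hash so that each participant / stage gets an
#' independent, reproducible stream. Result is always in [0, 2^31 - 1).
#'
#' @param seed parent seed.
#' @param ... integer offsets (stream indices) combined into the child seed.
#' @return integer child seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# semitone (relative to C4 = 0, A440 equal temperament) -> frequency in Hz
semitone_to_hz <- function(semitone) {
  440 * 2^((semitone - 9) / 12)
}

hz_to_semitone <- function(hz) {
  9 + 12 * log2(hz / 440)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
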