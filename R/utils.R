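# Internal helpers shared across modules.

#' @keywords internal
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

#' Derive a reproducible sub-seed for a named component stream.
#'
#' One global integer seed drives every source of randomness; each component
#' (cohort geometry, tile noise, model init, split resampling, ...) draws from
#' its own stream so that adding a consumer never perturbs the others. The
#' stream seed is a deterministic integer mix of the global seed and the
#' stream name, kept below 2^31.
#'
#' @param seed integer global seed.
#' @param stream character stream name.
#' @return an integer usable with [set.seed()].
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 69069 + h * 1013 + 17) %% 2147483587)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

check_prob_matrix <- function(probs, tol = 1e-6) {
  probs <- as.matrix(probs)
  if (any(probs < -tol) || any(abs(rowSums(probs) - 1) > 1e-4))
    stop("'probs' rows must be points on the probability simplex", call. = FALSE)
  probs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
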