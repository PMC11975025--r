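# Spectral normalization of weight matrices via power iteration.

#' Create power-iteration state for a weight matrix
#' @param weight numeric matrix.
#' @return list with unit left-singular vector estimate `u` and last spectral
#'   estimate `lambda` (class `spectral_state`).
#' @export
spectral_state <- function(weight) {
  u <- stats::rnorm(nrow(weight))
  u <- u / sqrt(sum(u^2))
  structure(list(u = u, lambda = NA_real_), class = "spectral_state")
}

power_iterate <- function(weight, u, n_iter) {
  for (i in seq_len(n_iter)) {
    v <- drop(crossprod(weight, u))
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(list(u = u, v = v, lambda = 0))
    v <- v / nv
    u <- drop(weight %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(list(u = u, v = v, lambda = 0))
    u <- u / nu
  }
  list(u = u, v = v, lambda = drop(crossprod(u, weight %*% v)))
}

#' Spectrally normalize a weight matrix
#'
#' Estimates the spectral norm (largest singular value) by power iteration
#' and rescales the matrix to `c * W / lambda` when the estimate exceeds the
#' bound `c`; otherwise the matrix is returned unchanged. This caps the
#' layer's Lipschitz constant at `c`, the ingredient that keeps a deep
#' feature extractor approximately distance-preserving.
#'
#' @param weight numeric matrix.
#' @param c positive spectral-norm bound.
#' @param state optional persistent `spectral_state` (re-used across training
#'   steps so one iteration per step suffices).
#' @param n_iter power iterations (default 50 for standalone calls; use 1
#'   with a persistent state inside a training loop).
#' @return list with `weight` (normalized matrix), `lambda` (spectral
#'   estimate) and the updated `state`.
#' @export
spectral_normalize <- function(weight, c = 1, state = NULL, n_iter = 50L) {
  stopifnot(is.matrix(weight), c > 0)
  if (all(weight == 0)) {
    warning("zero weight matrix: spectral norm is 0, returning unchanged")
    st <- state %||% spectral_state(weight)
    st$lambda <- 0
    return(list(weight = weight, lambda = 0, state = st))
  }
  st <- state %||% spectral_state(weight)
  pi <- power_iterate(weight, st$u, n_iter)
  st$u <- pi$u
  st$lambda <- pi$lambda
  w <- if (c < pi$lambda) c * weight / pi$lambda else weight
  list(weight = w, lambda = pi$lambda, state = st)
}
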