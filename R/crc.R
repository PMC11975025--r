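# Conformal risk control: calibrates a probability threshold rho so that the
# expected miscoverage of the threshold sets G_rho(x) = {k : f(x)_k >= 1-rho}
# stays below alpha even when the calibration stream contains undetected OOD
# units (whose true label is never covered). Miscoverage is monotone
# non-increasing in rho, so the smallest feasible rho is found by bisection.

crc_coverage_at <- function(rho, probs, labels) {
  ok <- !is.na(labels)
  covered <- rep(FALSE, length(labels))
  covered[ok] <- probs[cbind(which(ok), labels[ok] + 1L)] >= 1 - rho
  mean(covered)
}

#' Calibrate a conformal risk controller
#'
#' Finds the smallest threshold `rho_hat` in `[0, 1]` whose empirical
#' coverage on the calibration stream reaches the finite-sample-corrected
#' target `(n + 1) * (1 - alpha) / n` (the analogue of split CP's
#' ceiling((R+1)(1-alpha)) rank; without the correction the expected test
#' coverage is biased low by about `(1 - alpha) / n`). Calibration units
#' with `NA` labels (undetected OOD) count as never covered, which is
#' exactly what makes the controller conservative under contamination. When
#' even `rho = 1` cannot reach the target (contamination fraction near or
#' above `alpha`), `rho_hat = 1` is returned with `feasible = FALSE`.
#'
#' @param probs n x K calibration probability matrix.
#' @param labels integer labels in `0..K-1`, `NA` for OOD units.
#' @param alpha target error level in (0, 1).
#' @param tolerance bisection tolerance on rho (default 1e-4).
#' @param max_iter bisection iteration cap (default 64).
#' @return object of class `crc` with `rho_hat`, `alpha`, `feasible`.
#' @export
crc <- function(probs, labels, alpha, tolerance = 1e-4, max_iter = 64L) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)
  probs <- check_prob_matrix(probs)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(probs), alpha > 0, alpha < 1)
  n <- nrow(probs)
  target <- min(1, (n + 1) * (1 - alpha) / n)
  if (crc_coverage_at(1, probs, labels) < target) {
    return(structure(list(rho_hat = 1, alpha = alpha, tolerance = tolerance,
                          feasible = FALSE), class = "crc"))
  }
  lo <- 0; hi <- 1
  if (crc_coverage_at(0, probs, labels) >= target) {
    hi <- 0
  } else {
    for (i in seq_len(max_iter)) {
      if (hi - lo <= tolerance) break
      mid <- (lo + hi) / 2
      if (crc_coverage_at(mid, probs, labels) >= target) hi <- mid else lo <- mid
    }
  }
  structure(list(rho_hat = hi, alpha = alpha, tolerance = tolerance,
                 feasible = TRUE), class = "crc")
}

#' @export
print.crc <- function(x, ...) {
  cat(sprintf("Conformal risk controller: alpha %.3g, rho_hat %.4f%s\n",
              x$alpha, x$rho_hat, if (x$feasible) "" else " [infeasible]"))
  invisible(x)
}

#' Prediction sets from a risk controller
#'
#' @param object a calibrated [crc()] controller.
#' @param probs n x K probability matrix.
#' @param labels optional true labels for categorization.
#' @param ... unused.
#' @return a `prediction_sets` object with
#'   `set = {k : probs[k] >= 1 - rho_hat}`.
#' @export
predict.crc <- function(object, probs, labels = NULL, ...) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)
  probs <- check_prob_matrix(probs)
  set <- probs >= 1 - object$rho_hat
  new_prediction_sets(set, labels)
}
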