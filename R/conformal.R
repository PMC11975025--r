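# Split (inductive) conformal prediction for classification.
#
# Nonconformity s(x, y) = 1 - f(x)_y; the calibration threshold q-hat is the
# ceiling((R+1)(1-alpha))-th smallest calibration score, which guarantees
# marginal coverage in [1-alpha, 1-alpha + 1/(R+1)] for exchangeable data.

#' Nonconformity score of labeled predictions
#'
#' @param probs n x K matrix (or length-K vector) of class probabilities.
#' @param labels integer labels in `0..K-1`.
#' @return numeric scores `1 - probs[label]`, in `[0, 1]`.
#' @export
nonconformity <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)
  probs <- check_prob_matrix(probs)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(probs)))
    stop("labels out of range 0..K-1", call. = FALSE)
  1 - probs[cbind(seq_len(nrow(probs)), labels + 1L)]
}

#' Calibrate a split conformal predictor
#'
#' @param scores calibration nonconformity scores (R >= 1).
#' @param alpha error level in (0, 1).
#' @return object of class `conformal` holding the threshold `q_hat` (the
#'   ceiling((R+1)(1-alpha))-th smallest score, or `Inf` when that index
#'   exceeds R, in which case every prediction set contains all labels).
#' @export
conformal <- function(scores, alpha) {
  if (length(scores) < 1L) stop("empty calibration scores", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  R <- length(scores)
  k <- ceiling((R + 1) * (1 - alpha))
  q_hat <- if (k > R) Inf else sort(scores)[k]
  structure(list(alpha = alpha, R = R, q_hat = q_hat, scores = scores),
            class = "conformal")
}

#' @export
print.conformal <- function(x, ...) {
  cat(sprintf("Split conformal predictor: alpha %.3g, R %d, q_hat %s\n",
              x$alpha, x$R,
              if (is.finite(x$q_hat)) sprintf("%.4f", x$q_hat) else "Inf"))
  invisible(x)
}

set_category <- function(set_matrix, labels = NULL) {
  size <- rowSums(set_matrix)
  K <- ncol(set_matrix)
  cat <- rep(NA_character_, nrow(set_matrix))
  cat[size == 0L] <- "empty"
  cat[size == K] <- "abstention"
  singleton <- size == 1L & K > 1L
  if (!is.null(labels)) {
    pred <- max.col(set_matrix, ties.method = "first") - 1L
    cat[singleton] <- ifelse(pred[singleton] == labels[singleton],
                             "single_correct", "single_incorrect")
  } else {
    cat[singleton] <- "single"
  }
  cat[is.na(cat)] <- "multi"  # 1 < size < K (only possible when K > 2)
  cat
}

#' Prediction sets from a calibrated conformal predictor
#'
#' The set contains every label whose nonconformity `1 - probs[k]` is at
#' most `q_hat` (ties included). Empty sets are representable and reported
#' as their own category. For binary problems the full set (size 2) is an
#' abstention.
#'
#' @param object a calibrated [conformal()] predictor.
#' @param probs n x K probability matrix.
#' @param labels optional true labels for categorization.
#' @param ... unused.
#' @return a `prediction_sets` object: logical n x K membership matrix
#'   `set`, `set_size`, and per-unit `category` (single_correct /
#'   single_incorrect / abstention / empty when labels are supplied).
#' @export
predict.conformal <- function(object, probs, labels = NULL, ...) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)
  probs <- check_prob_matrix(probs)
  set <- (1 - probs) <= object$q_hat
  new_prediction_sets(set, labels)
}

new_prediction_sets <- function(set, labels = NULL) {
  structure(list(set = set, set_size = rowSums(set),
                 category = set_category(set, labels),
                 labels = labels),
            class = "prediction_sets")
}

#' @export
print.prediction_sets <- function(x, ...) {
  cat(sprintf("Prediction sets: %d units, mean size %.3f\n",
              nrow(x$set), mean(x$set_size)))
  print(table(x$category))
  invisible(x)
}

#' Evaluate prediction sets against true labels
#'
#' Coverage is the fraction of sets containing the truth; efficiency the
#' mean set size; the determinate-answer (DA) error rate is the fraction of
#' incorrect singletons among all singleton predictions (reported `NA` when
#' no singletons exist).
#'
#' @param sets a `prediction_sets` object.
#' @param labels integer true labels in `0..K-1`. For units whose label is
#'   conceptually undefined (e.g. undetected OOD), pass `NA`: they count as
#'   never covered.
#' @return list with `coverage`, `mean_set_size`, `breakdown` (named counts)
#'   and `da_error`.
#' @export
conformal_evaluate <- function(sets, labels) {
  stopifnot(inherits(sets, "prediction_sets"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(sets$set))
    stop("sets and labels length mismatch", call. = FALSE)
  covered <- rep(FALSE, length(labels))
  ok <- !is.na(labels)
  covered[ok] <- sets$set[cbind(which(ok), labels[ok] + 1L)]
  cat <- set_category(sets$set, labels)
  n_sc <- sum(cat == "single_correct")
  n_si <- sum(cat == "single_incorrect")
  breakdown <- c(single_correct = n_sc, single_incorrect = n_si,
                 abstention = sum(cat == "abstention"),
                 empty = sum(cat == "empty"))
  da <- if (n_sc + n_si == 0L) NA_real_ else n_si / (n_sc + n_si)
  list(coverage = mean(covered), mean_set_size = mean(sets$set_size),
       breakdown = breakdown, da_error = da)
}
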