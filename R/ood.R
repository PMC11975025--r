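# Out-of-distribution scoring, detection evaluation, distribution-shift
# control, and the guarded OOD-detection + conformal-risk-control pipeline.

#' Probability-based OOD score of one unit
#'
#' @param tile_probs n x K matrix of tile class probabilities for one
#'   slide/patient (all the unit's tiles pooled).
#' @return `1 - mean(max_k p_k)`, in `[0, 1 - 1/K]`; higher = more OOD.
#' @export
probability_ood_score <- function(tile_probs) {
  if (is.null(dim(tile_probs))) tile_probs <- matrix(tile_probs, 1L)
  if (nrow(tile_probs) == 0L) stop("empty unit: no tiles to score", call. = FALSE)
  1 - mean(apply(tile_probs, 1L, max))
}

#' Uncertainty-based OOD score of one unit
#'
#' Represents the unit by its most confident tiles: the mean uncertainty of
#' the `delta` lowest-uncertainty tiles (`delta` clipped to the tile count).
#' In-D units have at least some low-uncertainty tiles; OOD units do not.
#'
#' @param tile_uncertainties per-tile uncertainty values of one unit.
#' @param delta number of lowest-uncertainty tiles used (default 200).
#' @return mean uncertainty over the `min(delta, N)` lowest tiles.
#' @export
uncertainty_ood_score <- function(tile_uncertainties, delta = 200L) {
  if (length(tile_uncertainties) == 0L) stop("empty unit: no tiles to score", call. = FALSE)
  stopifnot(delta >= 1)
  k <- min(delta, length(tile_uncertainties))
  mean(sort(tile_uncertainties)[seq_len(k)])
}

#' Per-unit OOD scores from tile-level predictions
#'
#' @param pred a `predictive_output` over tiles.
#' @param units per-tile unit ids (e.g. patient or slide ids).
#' @param mode "probability" or "uncertainty".
#' @param delta lowest-uncertainty tile count (uncertainty mode).
#' @return named numeric vector of unit scores.
#' @export
unit_ood_scores <- function(pred, units, mode = c("uncertainty", "probability"),
                            delta = 200L) {
  mode <- match.arg(mode)
  ids <- unique(units)
  vapply(stats::setNames(ids, ids), function(u) {
    idx <- units == u
    if (mode == "probability") probability_ood_score(pred$probs[idx, , drop = FALSE])
    else uncertainty_ood_score(pred$uncertainty[idx], delta)
  }, numeric(1))
}

#' Fit an OOD decision threshold
#'
#' @param scores_in In-D reference unit scores (threshold basis "fpr" uses
#'   these alone: the threshold is the (1-fpr) empirical quantile, so a
#'   fraction `target` of In-D units scores above it).
#' @param scores_out OOD reference scores (required for basis "tpr" or
#'   "precision").
#' @param basis one of "fpr", "tpr", "precision".
#' @param target operating value for the chosen basis.
#' @param mode,delta bookkeeping of how scores were computed.
#' @return object of class `ood_scorer` with a finite `threshold`; units
#'   scoring strictly above it are declared OOD.
#' @export
ood_scorer <- function(scores_in, scores_out = NULL,
                       basis = c("fpr", "tpr", "precision"), target = 0.05,
                       mode = "uncertainty", delta = 200L) {
  basis <- match.arg(basis)
  stopifnot(length(scores_in) > 0L, target >= 0, target <= 1)
  thr <- switch(basis,
    fpr = {
      s <- sort(scores_in)
      n <- length(s)
      k <- ceiling((1 - target) * n)
      if (k < 1L) -Inf else s[k]
    },
    tpr = {
      stopifnot(!is.null(scores_out))
      s <- sort(scores_out)
      n <- length(s)
      k <- floor((1 - target) * n)
      # target = 1: threshold sits just below the smallest OOD score so that
      # every OOD unit is rejected while low-scoring In-D units survive
      if (k < 1L) s[1L] - max(1e-12, abs(s[1L]) * 1e-9) else s[k]
    },
    precision = {
      stopifnot(!is.null(scores_out))
      sw <- detection_sweep(scores_in, scores_out)
      ok <- sw$precision >= target
      if (!any(ok)) max(c(scores_in, scores_out))
      else sw$threshold[ok][which.max(sw$tpr[ok])]
    })
  structure(list(threshold = thr, basis = basis, target = target,
                 mode = mode, delta = delta), class = "ood_scorer")
}

#' @export
print.ood_scorer <- function(x, ...) {
  cat(sprintf("OOD scorer [%s]: threshold %.4g (basis %s = %.3g, delta %d)\n",
              x$mode, x$threshold, x$basis, x$target, x$delta))
  invisible(x)
}

rank_auroc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

detection_sweep <- function(scores_in, scores_out) {
  thr <- sort(unique(c(scores_in, scores_out, -Inf)))
  t(vapply(thr, function(t) {
    tp <- sum(scores_out > t); fp <- sum(scores_in > t)
    c(threshold = t, tpr = tp / length(scores_out),
      fpr = fp / length(scores_in),
      precision = if (tp + fp == 0) 1 else tp / (tp + fp))
  }, numeric(4))) |> as.data.frame()
}

#' Evaluate OOD detection
#'
#' OOD is the positive class throughout. AUROC is the exact rank
#' (Mann-Whitney) statistic; operating points come from a full threshold
#' sweep; the FPR-based threshold is computed on In-D scores only.
#'
#' @param scores_in In-D unit scores.
#' @param scores_out OOD unit scores.
#' @param precision_target precision at which to report TPR (default 0.95).
#' @param fpr_target FPR at which to report the threshold (default 0.2).
#' @return list with `auroc`, `pr_curve` (threshold/tpr/fpr/precision),
#'   `tpr_at_precision`, `threshold_at_fpr`.
#' @export
evaluate_detection <- function(scores_in, scores_out,
                               precision_target = 0.95, fpr_target = 0.2) {
  stopifnot(length(scores_in) > 0L, length(scores_out) > 0L)
  if (stats::var(c(scores_in, scores_out)) == 0) {
    warning("constant scores: detection is uninformative, AUROC = 0.5")
    auroc <- 0.5
  } else {
    auroc <- rank_auroc(scores_out, scores_in)
  }
  sw <- detection_sweep(scores_in, scores_out)
  ok <- sw$precision >= precision_target
  list(auroc = auroc, pr_curve = sw,
       tpr_at_precision = if (any(ok)) max(sw$tpr[ok]) else 0,
       threshold_at_fpr = ood_scorer(scores_in, basis = "fpr",
                                     target = fpr_target)$threshold)
}

#' Distribution-shift control filter
#'
#' Excludes external units whose OOD score exceeds a reference threshold
#' before inference or conformal calibration.
#'
#' @param unit_scores named numeric vector of external unit scores.
#' @param threshold decision value (fit on In-D reference scores).
#' @return list with `retained` (unit ids), `excluded`, and counts.
#' @export
dsc_filter <- function(unit_scores, threshold) {
  keep <- unit_scores <= threshold
  list(retained = names(unit_scores)[keep],
       excluded = names(unit_scores)[!keep],
       n_retained = sum(keep), n_excluded = sum(!keep),
       excluded_fraction = mean(!keep))
}

#' Guarded inference: OOD rejection plus conformal sets
#'
#' Units scoring above the OOD threshold are rejected; survivors receive
#' prediction sets from the supplied set predictor (a [conformal()] or
#' [crc()] object). Coverage is reported both over In-D survivors (the
#' guarantee of interest) and over all survivors; OOD survivors count as
#' never covered.
#'
#' @param probs n x K unit probability matrix (test stream, In-D and OOD
#'   mixed).
#' @param labels integer labels, `NA` for OOD units.
#' @param is_ood logical ground-truth flags (evaluation only).
#' @param ood_scores per-unit OOD scores.
#' @param threshold OOD decision threshold (units above it are rejected).
#' @param predictor a calibrated `conformal` or `crc` object.
#' @return list with per-unit `outcome` data.frame (rejected, set_size,
#'   covered) and summary fields `coverage_ind_survivors`,
#'   `coverage_survivors`, `mean_set_size`, `n_rejected`, `n_survivors`,
#'   `detector_tpr`, `detector_fpr`.
#' @export
guarded_inference <- function(probs, labels, is_ood, ood_scores, threshold,
                              predictor) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)
  n <- nrow(probs)
  stopifnot(length(labels) == n, length(is_ood) == n, length(ood_scores) == n)
  rejected <- ood_scores > threshold
  outcome <- data.frame(rejected = rejected, set_size = NA_integer_,
                        covered = NA)
  if (all(rejected)) {
    warning("all units rejected as OOD: empty inference result")
    return(list(outcome = outcome, coverage_ind_survivors = NA_real_,
                coverage_survivors = NA_real_, mean_set_size = NA_real_,
                n_rejected = n, n_survivors = 0L,
                detector_tpr = mean(rejected[is_ood]),
                detector_fpr = mean(rejected[!is_ood])))
  }
  surv <- which(!rejected)
  sets <- stats::predict(predictor, probs[surv, , drop = FALSE])
  covered <- rep(FALSE, length(surv))
  ok <- !is.na(labels[surv])
  covered[ok] <- sets$set[cbind(which(ok), labels[surv][ok] + 1L)]
  outcome$set_size[surv] <- sets$set_size
  outcome$covered[surv] <- covered
  ind_surv <- !is_ood[surv]
  list(outcome = outcome,
       coverage_ind_survivors = if (any(ind_surv)) mean(covered[ind_surv]) else NA_real_,
       coverage_survivors = mean(covered),
       mean_set_size = mean(sets$set_size),
       n_rejected = sum(rejected), n_survivors = length(surv),
       detector_tpr = if (any(is_ood)) mean(rejected[is_ood]) else NA_real_,
       detector_fpr = if (any(!is_ood)) mean(rejected[!is_ood]) else NA_real_)
}
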