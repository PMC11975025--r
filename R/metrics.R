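# Hierarchical aggregation (tile -> slide -> patient) and evaluation
# metrics: accuracy/AUROC, demographic fairness gaps, attention efficiency.

#' Aggregate tile probabilities up the slide/patient hierarchy
#'
#' Two-stage unweighted means: slide probabilities are the mean of member
#' tile probabilities, patient probabilities the mean of member slide
#' probabilities (not tile-pooled). Eliminated tiles must be removed before
#' calling; slides with zero remaining tiles are simply absent.
#'
#' @param tile_probs n x K matrix of tile class probabilities.
#' @param manifest data.frame aligned with `tile_probs` rows, with columns
#'   slide_id, patient_id, label and optionally sex, race, is_ood.
#' @return list with data.frames `slide` and `patient`; probability columns
#'   are named `p0..p{K-1}`.
#' @export
aggregate_hierarchy <- function(tile_probs, manifest) {
  if (is.null(dim(tile_probs))) tile_probs <- matrix(tile_probs, ncol = 1L)
  stopifnot(nrow(tile_probs) == nrow(manifest))
  K <- ncol(tile_probs)
  pcols <- paste0("p", seq_len(K) - 1L)
  slide_p <- rowsum(tile_probs, manifest$slide_id) /
    as.vector(table(manifest$slide_id)[sort(unique(manifest$slide_id))])
  meta_cols <- intersect(c("patient_id", "label", "sex", "race", "is_ood"),
                         names(manifest))
  slide_meta <- manifest[!duplicated(manifest$slide_id),
                         c("slide_id", meta_cols), drop = FALSE]
  slide_meta <- slide_meta[match(rownames(slide_p), slide_meta$slide_id), ]
  slide <- cbind(slide_meta, stats::setNames(as.data.frame(slide_p), pcols))
  rownames(slide) <- NULL
  patient_p <- rowsum(as.matrix(slide[, pcols, drop = FALSE]), slide$patient_id) /
    as.vector(table(slide$patient_id)[sort(unique(slide$patient_id))])
  pat_meta <- slide[!duplicated(slide$patient_id),
                    intersect(c("patient_id", "label", "sex", "race", "is_ood"),
                              names(slide)), drop = FALSE]
  pat_meta <- pat_meta[match(rownames(patient_p), pat_meta$patient_id), ]
  patient <- cbind(pat_meta, stats::setNames(as.data.frame(patient_p), pcols))
  rownames(patient) <- NULL
  list(slide = slide, patient = patient)
}

#' Accuracy and AUROC of probabilistic binary predictions
#'
#' Accuracy uses the 0.5 decision threshold (argmax); AUROC is the exact
#' rank statistic on the class-1 probability, `NA` when only one class is
#' present.
#'
#' @param probs n x K probability matrix (K = 2 for AUROC).
#' @param labels integer labels in `0..K-1`.
#' @return list with `accuracy` and `auroc`.
#' @export
classification_metrics <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- cbind(1 - probs, probs)
  labels <- as.integer(labels)
  acc <- mean(max.col(probs, ties.method = "first") - 1L == labels)
  auroc <- if (length(unique(labels)) < 2L || ncol(probs) != 2L) NA_real_
           else rank_auroc(probs[labels == 1L, 2L], probs[labels == 0L, 2L])
  list(accuracy = acc, auroc = auroc)
}

#' Fairness gap across demographic subgroups
#'
#' Per-group mean of a per-unit metric (e.g. correctness for accuracy,
#' prediction-set size for CP efficiency); the gap is the difference between
#' the best- and worst-performing groups. Groups smaller than
#' `min_group_size` units are merged into "Others" before computing.
#'
#' @param values per-unit metric values (e.g. 0/1 correctness, set sizes).
#' @param subgroup per-unit group labels.
#' @param metric name used in the report.
#' @param min_group_size merge threshold (default 20 units).
#' @return object of class `fairness_report`: `group_values`, `gap`
#'   (max - min, `NA` with fewer than 2 groups after merging), `metric`.
#' @export
fairness_gaps <- function(values, subgroup, metric = "accuracy",
                          min_group_size = 20L) {
  stopifnot(length(values) == length(subgroup))
  subgroup <- as.character(subgroup)
  sizes <- table(subgroup)
  small <- names(sizes)[sizes < min_group_size]
  subgroup[subgroup %in% small] <- "Others"
  gv <- tapply(values, subgroup, mean)
  gap <- if (length(gv) < 2L) NA_real_ else max(gv) - min(gv)
  structure(list(metric = metric, group_values = gv, gap = gap,
                 group_sizes = table(subgroup)),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("Fairness report [%s]: gap = %s\n", x$metric,
              if (is.na(x$gap)) "NA (single group)" else sprintf("%.4f", x$gap)))
  print(round(x$group_values, 4))
  invisible(x)
}

#' Attention efficiency against a relevance reference
#'
#' Removes the fraction `P` of tiles with the lowest attention and reports
#' the share of the kept (high-attention) tiles that fall in the reference
#' relevant set. Ties are broken by stable tile order.
#'
#' @param attention per-tile attention scores.
#' @param relevance per-tile 0/1 relevance reference.
#' @param P fraction of lowest-attention tiles removed, in `[0, 1)`.
#' @return fraction of kept tiles that are relevant.
#' @export
attention_efficiency <- function(attention, relevance, P) {
  stopifnot(length(attention) == length(relevance), P >= 0, P < 1)
  if (all(attention == 0)) stop("all-zero attention scores", call. = FALSE)
  n <- length(attention)
  n_keep <- ceiling((1 - P) * n)
  ord <- order(-attention)  # stable: ties keep original order
  kept <- ord[seq_len(n_keep)]
  mean(relevance[kept] == 1)
}
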