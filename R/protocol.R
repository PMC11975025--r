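# End-to-end evaluation protocol: patient-level 65/15/20 split, repeated
# model replicates, repeated conformal calibration/test splits, full summary.

split_patients <- function(patients, seed, fractions = c(0.65, 0.15, 0.20)) {
  with_stream(seed, "protocol-split", {
    p <- sample(unique(patients))
    n <- length(p)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    list(train = p[seq_len(n_tr)],
         val = p[n_tr + seq_len(n_va)],
         test = p[(n_tr + n_va + 1L):n])
  })
}

#' Run the full evaluation protocol on a synthetic cohort
#'
#' For each model replicate: generate a cohort, split patients 65/15/20
#' (train/validation/calibration+test), train the SNGP tile classifier,
#' aggregate tile probabilities to patients, then resample the
#' calibration/test pool `n_cp_splits` times, calibrating split CP at each
#' error level and evaluating coverage, set size, classification breakdown
#' and DA error. Patient-level accuracy/AUROC and fairness gaps (sex, race)
#' are computed per replicate.
#'
#' @param config a [cohort_config()]; the replicate index is folded into its
#'   seed so replicates see independent cohorts.
#' @param model_config an [sngp_config()].
#' @param alpha error levels to calibrate at.
#' @param n_replicates independently trained models (default 2 at desk
#'   scale; the full protocol uses 20).
#' @param n_cp_splits calibration/test resamples per replicate (default 20;
#'   the full protocol uses 500).
#' @param calibration_fraction fraction of the held-out pool used for
#'   calibration in each CP split.
#' @param seed global seed.
#' @param out_dir optional directory for summary JSON + per-unit TSVs.
#' @return a summary list (also written to `out_dir/summary.json` if given)
#'   with per-alpha coverage/size/breakdown/DA error, accuracy, AUROC and
#'   fairness gaps.
#' @export
reproduce_protocol <- function(config = cohort_config(),
                               model_config = sngp_config(D = 256L),
                               alpha = c(0.1, 0.05, 0.01),
                               n_replicates = 2L, n_cp_splits = 20L,
                               calibration_fraction = 0.5,
                               seed = config$seed, out_dir = NULL) {
  per_alpha <- stats::setNames(lapply(alpha, function(a)
    list(coverage = c(), size = c(), da_error = c(),
         breakdown = NULL)), paste0("alpha_", alpha))
  acc <- auroc <- c()
  gaps_sex <- gaps_race <- c()
  for (rep_i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- stream_seed(seed, paste0("replicate-", rep_i))
    cohort <- generate_cohort(cfg)
    m <- cohort$manifest
    sp <- split_patients(m$patient_id, cfg$seed)
    tr <- tile_subset(cohort, m$patient_id %in% sp$train)
    va <- tile_subset(cohort, m$patient_id %in% sp$val)
    te <- tile_subset(cohort, m$patient_id %in% sp$test)
    mc <- model_config
    mc$seed <- cfg$seed
    model <- sngp(tr, config = mc, validation = list(x = va$embeddings,
                                                     y = va$manifest$label))
    pred <- predict(model, te)
    agg <- aggregate_hierarchy(pred$probs, te$manifest)
    pat <- agg$patient
    pp <- as.matrix(pat[, c("p0", "p1")])
    cm <- classification_metrics(pp, pat$label)
    acc <- c(acc, cm$accuracy); auroc <- c(auroc, cm$auroc)
    correct <- (max.col(pp, ties.method = "first") - 1L) == pat$label
    gaps_sex <- c(gaps_sex, fairness_gaps(correct, pat$sex, "accuracy",
                                          min_group_size = 5L)$gap)
    gaps_race <- c(gaps_race, fairness_gaps(correct, pat$race, "accuracy",
                                            min_group_size = 5L)$gap)
    n_pat <- nrow(pat)
    R <- max(2L, round(calibration_fraction * n_pat))
    splits <- with_stream(cfg$seed, "cp-splits",
                          lapply(seq_len(n_cp_splits),
                                 function(i) sample(n_pat, R)))
    for (a in alpha) {
      key <- paste0("alpha_", a)
      for (s in splits) {
        cal_scores <- nonconformity(pp[s, , drop = FALSE], pat$label[s])
        cp <- conformal(cal_scores, a)
        sets <- predict(cp, pp[-s, , drop = FALSE], labels = pat$label[-s])
        ev <- conformal_evaluate(sets, pat$label[-s])
        per_alpha[[key]]$coverage <- c(per_alpha[[key]]$coverage, ev$coverage)
        per_alpha[[key]]$size <- c(per_alpha[[key]]$size, ev$mean_set_size)
        per_alpha[[key]]$da_error <- c(per_alpha[[key]]$da_error, ev$da_error)
        per_alpha[[key]]$breakdown <- rbind(per_alpha[[key]]$breakdown, ev$breakdown)
      }
    }
  }
  summary <- list(
    n_replicates = n_replicates, n_cp_splits = n_cp_splits,
    accuracy = mean(acc), auroc = mean(auroc),
    fairness = list(sex_accuracy_gap = mean(gaps_sex),
                    race_accuracy_gap = mean(gaps_race)),
    conformal = lapply(per_alpha, function(x) list(
      coverage = mean(x$coverage),
      mean_set_size = mean(x$size),
      da_error = if (all(is.na(x$da_error))) NA_real_
                 else mean(x$da_error, na.rm = TRUE),
      breakdown = as.list(colMeans(x$breakdown))
    ))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary_json(summary, file.path(out_dir, "summary.json"))
    write_run_manifest(out_dir, config, seed)
  }
  summary
}
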