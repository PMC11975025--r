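# Simulation studies: the package's own evaluation experiments, run at desk
# scale on synthetic cohorts. These drive both the test suite and the
# reproduction script.

#' Split-CP validity study
#'
#' For each generator seed: trains the SNGP tile classifier, aggregates to
#' patient probabilities, then resamples calibration/test splits and records
#' empirical coverage at each error level.
#'
#' @param alpha error levels.
#' @param n_seeds generator/model seeds.
#' @param n_splits calibration/test resamples per seed.
#' @param R calibration patients per split.
#' @param n_patients_per_class cohort size (must exceed R/2 comfortably so a
#'   test set remains).
#' @param model_config an [sngp_config()].
#' @param seed global seed.
#' @return list with `coverage` (matrix seeds x alpha of mean coverage),
#'   `per_split` (list of per-split coverage vectors by alpha), `R`.
#' @export
cp_validity_study <- function(alpha = c(0.1, 0.05, 0.01), n_seeds = 5L,
                              n_splits = 500L, R = 100L,
                              n_patients_per_class = 100L,
                              model_config = sngp_config(D = 256L, epochs = 15L),
                              seed = 1L) {
  cov <- matrix(NA_real_, n_seeds, length(alpha),
                dimnames = list(NULL, paste0("alpha_", alpha)))
  per_split <- stats::setNames(vector("list", length(alpha)),
                               paste0("alpha_", alpha))
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(n_patients_per_class = n_patients_per_class,
                         seed = stream_seed(seed, paste0("cpv-", s)))
    cohort <- generate_cohort(cfg)
    mc <- model_config; mc$seed <- cfg$seed
    model <- sngp(cohort, config = mc)
    pred <- predict(model, cohort)
    pat <- aggregate_hierarchy(pred$probs, cohort$manifest)$patient
    sc <- nonconformity(as.matrix(pat[, c("p0", "p1")]), pat$label)
    n_pat <- length(sc)
    splits <- with_stream(cfg$seed, "cpv-splits",
                          lapply(seq_len(n_splits), function(i) sample(n_pat, R)))
    for (a_i in seq_along(alpha)) {
      covs <- vapply(splits, function(cal) {
        q <- conformal(sc[cal], alpha[a_i])$q_hat
        mean(sc[-cal] <= q)
      }, numeric(1))
      cov[s, a_i] <- mean(covs)
      per_split[[a_i]] <- c(per_split[[a_i]], covs)
    }
  }
  list(coverage = cov, per_split = per_split, R = R)
}

guarded_unit_scores <- function(model, cohort, delta = 200L) {
  pred <- predict(model, cohort)
  pat <- aggregate_hierarchy(pred$probs, cohort$manifest)$patient
  u <- unit_ood_scores(pred, cohort$manifest$patient_id, mode = "uncertainty",
                       delta = delta)
  pat$ood_score <- u[pat$patient_id]
  pat
}

#' OOD-guarded conformal coverage study
#'
#' Per generator seed: trains SNGP on a training cohort, scores an
#' independent In-D evaluation cohort and a displaced OOD cohort at patient
#' level (uncertainty-based OOD score), then resamples contaminated
#' calibration/test streams. Three regimes are measured: (1) guarded
#' inference (OOD threshold at FPR `fpr` on the calibration In-D scores +
#' CRC calibrated on post-filter survivors) across OOD-to-In-D ratios;
#' (2) a detector-TPR sweep with standard split CP over retained units;
#' (3) the unguarded regime (no detection, plain CP) at ratio 1, whose
#' coverage over all units dilutes toward (1 - alpha)/2.
#'
#' @param ratios OOD-to-In-D ratios for the guarded regime.
#' @param tpr_targets detector TPR operating points for the sweep.
#' @param alpha error level.
#' @param n_seeds generator/model seeds.
#' @param n_splits resampled splits per seed.
#' @param fpr In-D false-positive rate of the OOD threshold.
#' @param model_config an [sngp_config()].
#' @param seed global seed.
#' @return list of data.frames: `guarded` (seed, ratio, split coverage over
#'   In-D survivors), `tpr_sweep` (seed, tpr, split coverage over retained
#'   units), `unguarded` (seed, split coverage over all units).
#' @export
guarded_coverage_study <- function(ratios = c(0.25, 0.5, 1, 2),
                                   tpr_targets = c(0.5, 0.8, 0.95, 1),
                                   alpha = 0.05, n_seeds = 5L, n_splits = 500L,
                                   fpr = 0.05,
                                   model_config = sngp_config(D = 256L, epochs = 15L),
                                   seed = 1L) {
  guarded <- tpr_sweep <- unguarded <- NULL
  n_eval <- 50L  # In-D calibration patients per split (and test patients)
  for (s in seq_len(n_seeds)) {
    base_seed <- stream_seed(seed, paste0("gcs-", s))
    cfg_tr <- cohort_config(seed = base_seed)
    cfg_ev <- cohort_config(seed = stream_seed(base_seed, "eval"))
    train <- generate_cohort(cfg_tr)
    eval_co <- generate_cohort(cfg_ev)
    ood_co <- generate_ood_cohort(cfg_ev, n_patients = 4L * n_eval + 20L)
    mc <- model_config; mc$seed <- base_seed
    model <- sngp(train, config = mc)
    pin <- guarded_unit_scores(model, eval_co)
    pout <- guarded_unit_scores(model, ood_co)
    n_in <- nrow(pin); n_out <- nrow(pout)
    probs_in <- as.matrix(pin[, c("p0", "p1")])
    probs_out <- as.matrix(pout[, c("p0", "p1")])
    splits <- with_stream(base_seed, "gcs-splits",
                          lapply(seq_len(n_splits), function(i)
                            list(cal = sample(n_in, n_eval),
                                 ood = sample(n_out))))
    for (sp in splits) {
      cal <- sp$cal
      te <- setdiff(seq_len(n_in), cal)[seq_len(n_eval)]
      thr <- ood_scorer(pin$ood_score[cal], basis = "fpr",
                        target = fpr)$threshold
      for (r in ratios) {
        n_ood <- round(r * n_eval)
        ood_cal <- sp$ood[seq_len(n_ood)]
        ood_te <- sp$ood[n_ood + seq_len(n_ood)]
        cal_probs <- rbind(probs_in[cal, ], probs_out[ood_cal, ])
        cal_labels <- c(pin$label[cal], rep(NA_integer_, n_ood))
        cal_scores <- c(pin$ood_score[cal], pout$ood_score[ood_cal])
        surv <- cal_scores <= thr
        ctrl <- crc(cal_probs[surv, , drop = FALSE], cal_labels[surv], alpha)
        g <- guarded_inference(
          rbind(probs_in[te, ], probs_out[ood_te, ]),
          c(pin$label[te], rep(NA_integer_, n_ood)),
          c(rep(FALSE, n_eval), rep(TRUE, n_ood)),
          c(pin$ood_score[te], pout$ood_score[ood_te]),
          thr, ctrl)
        guarded <- rbind(guarded, data.frame(
          seed = s, ratio = r, coverage = g$coverage_ind_survivors,
          mean_set_size = g$mean_set_size, tpr = g$detector_tpr))
      }
      # TPR sweep and unguarded dilution at ratio 1
      ood_cal <- sp$ood[seq_len(n_eval)]
      ood_te <- sp$ood[n_eval + seq_len(n_eval)]
      cp <- conformal(nonconformity(probs_in[cal, ], pin$label[cal]), alpha)
      mix_probs <- rbind(probs_in[te, ], probs_out[ood_te, ])
      mix_labels <- c(pin$label[te], rep(NA_integer_, n_eval))
      mix_ood <- c(rep(FALSE, n_eval), rep(TRUE, n_eval))
      mix_scores <- c(pin$ood_score[te], pout$ood_score[ood_te])
      for (tt in tpr_targets) {
        # operating point set on the evaluated stream's OOD scores, so the
        # realized TPR equals the target (a ROC-style threshold sweep)
        thr_t <- ood_scorer(pin$ood_score[cal], pout$ood_score[ood_te],
                            basis = "tpr", target = tt)$threshold
        g <- guarded_inference(mix_probs, mix_labels, mix_ood, mix_scores,
                               thr_t, cp)
        tpr_sweep <- rbind(tpr_sweep, data.frame(
          seed = s, tpr_target = tt, tpr = g$detector_tpr,
          coverage = g$coverage_survivors))
      }
      g0 <- guarded_inference(mix_probs, mix_labels, mix_ood, mix_scores,
                              threshold = Inf, predictor = cp)
      unguarded <- rbind(unguarded, data.frame(seed = s,
                                               coverage = g0$coverage_survivors))
    }
  }
  list(guarded = guarded, tpr_sweep = tpr_sweep, unguarded = unguarded,
       alpha = alpha)
}

#' Paired EAT comparison study
#'
#' Per seed: trains (a) the plain SNGP model, (b) SNGP-EAT (cluster-mode
#' elimination on the tile representations, then retraining; inference-time
#' tiles falling in the ambiguous cluster are excluded with the same fitted
#' index), and (c) SNGP-RE (rate-matched random elimination, then
#' retraining). Reports patient-level accuracy on an independent test
#' cohort.
#'
#' The study cohorts use modest class separation and small slides:
#' elimination can only help when the informative signal per slide is
#' imperfect and diluted, so the comparison is run off the accuracy ceiling
#' — the regime tile filtering targets. Clustering runs on the raw tile
#' embeddings, which in this pipeline are the tile representations the
#' classifier consumes.
#'
#' @param n_seeds paired seeds.
#' @param ambiguous_fraction cohort ambiguity level.
#' @param class_separation distance between class centroids in scale units.
#' @param tiles_per_slide tile-count range per slide (small slides amplify
#'   weak-supervision noise).
#' @param model_config an [sngp_config()].
#' @param seed global seed.
#' @return data.frame with one row per seed: accuracy of base / eat / re.
#' @export
eat_paired_study <- function(n_seeds = 20L, ambiguous_fraction = 2 / 3,
                             class_separation = 2.5,
                             tiles_per_slide = c(8L, 16L),
                             model_config = sngp_config(D = 128L, epochs = 15L),
                             seed = 1L) {
  means <- matrix(0, 3L, 8L)
  means[1, 1] <- -class_separation / 2
  means[2, 1] <- class_separation / 2
  means[3, 2] <- 2.5
  res <- NULL
  for (s in seq_len(n_seeds)) {
    bs <- stream_seed(seed, paste0("eat-", s))
    cfg_tr <- cohort_config(ambiguous_fraction = ambiguous_fraction,
                            cluster_means = means,
                            tiles_per_slide = tiles_per_slide, seed = bs)
    cfg_te <- cohort_config(ambiguous_fraction = ambiguous_fraction,
                            cluster_means = means,
                            tiles_per_slide = tiles_per_slide,
                            seed = stream_seed(bs, "test"))
    tr <- generate_cohort(cfg_tr)
    te <- generate_cohort(cfg_te)
    mc <- model_config; mc$seed <- bs
    pat_acc <- function(model, tiles) {
      pred <- predict(model, tiles)
      pat <- aggregate_hierarchy(pred$probs, tiles$manifest)$patient
      classification_metrics(as.matrix(pat[, c("p0", "p1")]), pat$label)$accuracy
    }
    base <- sngp(tr, config = mc)
    acc_base <- pat_acc(base, te)
    idx <- ambiguity_index("cluster", embeddings = tr$embeddings,
                           labels = tr$manifest$label, k = 3L, seed = bs)
    el_tr <- suppressWarnings(eliminate(tr, idx))
    # a misfired dominance rule can gut the training set; that seed scores NA
    acc_eat <- if (n_tiles(el_tr$tiles) == 0L ||
                   length(unique(el_tr$tiles$manifest$label)) < 2L) NA_real_
    else {
      eat_model <- sngp(el_tr$tiles, config = mc)
      el_te <- suppressWarnings(eliminate(te, idx))
      pat_acc(eat_model, el_te$tiles)
    }
    ridx <- ambiguity_index("random", retain_rate = 1 - el_tr$removed_fraction,
                            seed = bs)
    er_tr <- suppressWarnings(eliminate(tr, ridx))
    re_model <- sngp(er_tr$tiles, config = mc)
    er_te <- suppressWarnings(eliminate(te, ridx))
    acc_re <- pat_acc(re_model, er_te$tiles)
    res <- rbind(res, data.frame(seed = s, base = acc_base, eat = acc_eat,
                                 re = acc_re))
  }
  res
}

#' Tile-retention study (foundation path)
#'
#' Trains an ABMIL bag classifier once, then re-runs inference under
#' per-slide threshold-mode EAT (ambiguity from the proxy tile classifier)
#' and per-slide random elimination at a grid of retention rates, without
#' retraining. Slide-level accuracy on an independent test cohort is
#' reported for both.
#'
#' @param retain_rates retention grid.
#' @param abmil_cfg an [abmil_config()].
#' @param seed global seed.
#' @return data.frame: retain_rate, accuracy_eat, accuracy_random.
#' @export
eat_retention_study <- function(retain_rates = c(1, 0.5, 0.1, 0.01),
                                abmil_cfg = abmil_config(hidden_sizes = c(32L, 24L),
                                                         D = 128L, epochs = 15L),
                                seed = 1L) {
  bs <- stream_seed(seed, "retention")
  cfg_tr <- cohort_config(seed = bs)
  cfg_te <- cohort_config(seed = stream_seed(bs, "test"))
  tr <- generate_cohort(cfg_tr)
  te <- generate_cohort(cfg_te)
  abmil_cfg$seed <- bs
  model <- abmil(tr, config = abmil_cfg)
  amb_te <- ambiguity_score(proxy_tile_probs(tr, te))
  slide_acc <- function(tiles) {
    pr <- predict(model, tiles)
    mean(max.col(pr$pred$probs) - 1L == pr$slides$label)
  }
  res <- NULL
  for (r in retain_rates) {
    thr_idx <- ambiguity_index("threshold", retain_rate = r, per_slide = TRUE)
    el <- eliminate(te, thr_idx, scores = amb_te)
    rnd_idx <- ambiguity_index("random", retain_rate = r, per_slide = TRUE,
                               seed = bs)
    elr <- eliminate(te, rnd_idx)
    res <- rbind(res, data.frame(retain_rate = r,
                                 accuracy_eat = slide_acc(el$tiles),
                                 accuracy_random = slide_acc(elr$tiles)))
  }
  res
}
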