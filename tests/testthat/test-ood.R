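# OOD scores, detection metrics, distribution-shift control, guarded
# inference.

test_that("probability and uncertainty OOD scores follow their formulas", {
  expect_equal(probability_ood_score(rbind(c(1, 0), c(0, 1))), 0)
  expect_equal(probability_ood_score(rbind(c(0.5, 0.5), c(0.5, 0.5))), 0.5)
  expect_equal(probability_ood_score(rbind(c(1, 0), c(0.6, 0.4))), 0.2)
  expect_error(probability_ood_score(matrix(0, 0, 2)), "empty")
  expect_equal(uncertainty_ood_score(1:10, delta = 3L), 2)
  expect_equal(uncertainty_ood_score(rep(0.4, 7), delta = 200L), 0.4)
  expect_equal(formals(uncertainty_ood_score)$delta, 200L)
})

test_that("detection AUROC matches the brute-force pairwise oracle", {
  set.seed(7)
  s_in <- rnorm(50)
  s_out <- rnorm(50, 1)
  det <- evaluate_detection(s_in, s_out)
  brute <- mean(outer(s_out, s_in, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(det$auroc, brute)
  # perfect separation
  expect_equal(evaluate_detection(rnorm(30), rnorm(30) + 100)$auroc, 1)
  # identical distributions: near 1/2
  same <- rnorm(400)
  expect_equal(evaluate_detection(same, same)$auroc, 0.5, tolerance = 2 / sqrt(400))
  expect_warning(det0 <- evaluate_detection(rep(1, 10), rep(1, 10)), "constant")
  expect_equal(det0$auroc, 0.5)
})

test_that("FPR-based thresholds exclude the right In-D fraction", {
  set.seed(9)
  ref <- rnorm(500)
  thr <- ood_scorer(ref, basis = "fpr", target = 0.2)$threshold
  expect_equal(mean(ref > thr), 0.2, tolerance = 0.01)
  # fresh In-D-like units: ~20% excluded
  new_scores <- setNames(rnorm(500), paste0("u", 1:500))
  f <- dsc_filter(new_scores, thr)
  expect_lt(abs(f$excluded_fraction - 0.2), 0.06)
  expect_equal(dsc_filter(new_scores, Inf)$n_excluded, 0L)
})

test_that("excluded fraction under DSC rises with the OOD shift", {
  m <- sep_model()
  ref <- unit_ood_scores(predict(m, sep_cohort()),
                         sep_cohort()$manifest$patient_id)
  thr <- ood_scorer(ref, basis = "fpr", target = 0.2)$threshold
  fracs <- vapply(c(1, 3, 8), function(shift) {
    cfg <- cohort_config(ambiguous_fraction = 0, ood_mean_shift = shift,
                         seed = 202L)
    oo <- generate_ood_cohort(cfg, 30L)
    sc <- unit_ood_scores(predict(m, oo), oo$manifest$patient_id)
    dsc_filter(sc, thr)$excluded_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[3], 0.9)
})

test_that("both OOD scores separate well-shifted cohorts near-perfectly", {
  m <- sep_model()
  co <- sep_cohort()
  cfg <- cohort_config(ambiguous_fraction = 0, ood_mean_shift = 8, seed = 202L)
  oo <- generate_ood_cohort(cfg, 30L)
  p_in <- predict(m, co); p_out <- predict(m, oo)
  for (mode in c("uncertainty", "probability")) {
    s_in <- unit_ood_scores(p_in, co$manifest$patient_id, mode = mode)
    s_out <- unit_ood_scores(p_out, oo$manifest$patient_id, mode = mode)
    expect_gte(evaluate_detection(s_in, s_out)$auroc, 0.99)
  }
})

test_that("guarded inference restores coverage; unguarded inference dilutes it", {
  set.seed(11)
  n <- 400
  make_in <- function(n) {
    p1 <- plogis(rnorm(n, 2.5))
    cbind(p1, 1 - p1)
  }
  probs_in <- make_in(n)
  labels_in <- as.integer(rbinom(n, 1, probs_in[, 2]))
  probs_ood <- cbind(runif(n, 0.3, 0.7)); probs_ood <- cbind(probs_ood, 1 - probs_ood)
  sc_in <- rnorm(n); sc_ood <- rnorm(n, 6)
  alpha <- 0.05
  cal <- 1:(n / 2); te <- (n / 2 + 1):n
  # no contamination: guarded == plain CP coverage
  cp <- conformal(nonconformity(probs_in[cal, ], labels_in[cal]), alpha)
  g0 <- guarded_inference(probs_in[te, ], labels_in[te], rep(FALSE, n / 2),
                          sc_in[te], threshold = Inf, predictor = cp)
  expect_equal(g0$coverage_ind_survivors,
               conformal_evaluate(predict(cp, probs_in[te, ]),
                                  labels_in[te])$coverage)
  # 1:1 mixture, near-perfect detector + CRC: coverage back at 1 - alpha
  thr <- ood_scorer(sc_in[cal], basis = "fpr", target = 0.05)$threshold
  mix_probs <- rbind(probs_in[cal, ], probs_ood[cal, ])
  mix_labels <- c(labels_in[cal], rep(NA_integer_, n / 2))
  mix_scores <- c(sc_in[cal], sc_ood[cal])
  surv <- mix_scores <= thr
  ctrl <- crc(mix_probs[surv, ], mix_labels[surv], alpha)
  g1 <- guarded_inference(rbind(probs_in[te, ], probs_ood[te, ]),
                          c(labels_in[te], rep(NA_integer_, n / 2)),
                          rep(c(FALSE, TRUE), each = n / 2),
                          c(sc_in[te], sc_ood[te]), thr, ctrl)
  expect_gte(g1$coverage_ind_survivors, 1 - alpha - 0.03)
  expect_equal(g1$detector_tpr, 1)
  # both safeguards off: coverage over all units dilutes to ~ (1 - alpha)/2
  g2 <- guarded_inference(rbind(probs_in[te, ], probs_ood[te, ]),
                          c(labels_in[te], rep(NA_integer_, n / 2)),
                          rep(c(FALSE, TRUE), each = n / 2),
                          c(sc_in[te], sc_ood[te]), threshold = Inf,
                          predictor = cp)
  expect_equal(g2$coverage_survivors, (1 - alpha) / 2, tolerance = 0.04)
  # all-rejected stream is reported, not crashed
  expect_warning(
    g3 <- guarded_inference(probs_in[1:5, ], labels_in[1:5], rep(FALSE, 5),
                            rep(10, 5), threshold = 0, predictor = cp),
    "rejected")
  expect_equal(g3$n_survivors, 0L)
})
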