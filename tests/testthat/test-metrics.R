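# Hierarchical aggregation, classification metrics, fairness, attention
# efficiency.

test_that("aggregation is a two-stage unweighted mean", {
  manifest <- data.frame(
    slide_id = c("s1", "s1", "s2", "s3"),
    patient_id = c("p1", "p1", "p1", "p2"),
    label = c(0L, 0L, 0L, 1L))
  probs <- cbind(c(0.2, 0.4, 0.6, 0.9))
  probs <- cbind(1 - probs, probs)
  agg <- aggregate_hierarchy(probs, manifest)
  expect_equal(agg$slide$p1[agg$slide$slide_id == "s1"], 0.3)
  # patient p1: mean of slide means (0.3, 0.6) = 0.45, not tile-pooled 0.4
  expect_equal(agg$patient$p1[agg$patient$patient_id == "p1"], 0.45)
  expect_equal(agg$patient$p1[agg$patient$patient_id == "p2"], 0.9)
})

test_that("aggregation equals the grand mean in the balanced one-slide case", {
  set.seed(3)
  manifest <- data.frame(
    slide_id = rep(paste0("s", 1:10), each = 4),
    patient_id = rep(paste0("p", 1:10), each = 4),
    label = rep(0:1, each = 20))
  probs <- matrix(runif(40), 40); probs <- cbind(probs, 1 - probs)
  colnames(probs) <- NULL
  agg <- aggregate_hierarchy(probs, manifest)
  grand <- rowsum(probs[, 1], manifest$patient_id) / 4
  expect_equal(agg$patient$p0[match(rownames(grand), agg$patient$patient_id)],
               as.vector(grand))
  # permutation of tiles within slides changes nothing
  perm <- sample(40)
  agg2 <- aggregate_hierarchy(probs[perm, ], manifest[perm, ])
  expect_equal(agg2$patient[order(agg2$patient$patient_id), ],
               agg$patient[order(agg$patient$patient_id), ],
               ignore_attr = TRUE)
})

test_that("classification metrics match brute-force oracles", {
  set.seed(4)
  p1 <- runif(30)
  labels <- rbinom(30, 1, p1)
  if (length(unique(labels)) < 2) labels[1:2] <- 0:1
  cm <- classification_metrics(cbind(1 - p1, p1), labels)
  brute <- mean(outer(p1[labels == 1], p1[labels == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(cm$auroc, brute)
  expect_equal(cm$accuracy, mean((p1 > 0.5) == labels))
  # cross-check against an independent AUROC implementation
  expect_equal(cm$auroc,
               as.numeric(suppressMessages(pROC::auc(labels, p1))))
  # perfect ranking and degenerate labels
  expect_equal(classification_metrics(cbind(1 - p1, p1),
                                      as.integer(p1 > 0.5))$auroc, 1)
  expect_true(is.na(classification_metrics(cbind(1 - p1, p1),
                                           rep(1L, 30))$auroc))
})

test_that("fairness gaps: max minus min with small-group merging", {
  vals <- c(rep(1, 18), rep(0.5, 2), rep(0.9, 30), rep(0.8, 30))
  grp <- c(rep("tiny", 20), rep("a", 30), rep("b", 30))
  fr <- fairness_gaps(vals, grp, min_group_size = 20L)
  # 20-unit group stays; check a 19-unit group is merged into Others
  fr19 <- fairness_gaps(vals[-1], grp[-1], min_group_size = 20L)
  expect_true("Others" %in% names(fr19$group_values))
  expect_false("tiny" %in% names(fr19$group_values))
  # known gap
  fr2 <- fairness_gaps(c(rep(0.9, 20), rep(0.8, 20), rep(0.85, 20)),
                       rep(c("x", "y", "z"), each = 20))
  expect_equal(fr2$gap, 0.1, tolerance = 1e-12)
  # identical groups: zero gap; single group: NA
  expect_equal(fairness_gaps(rep(1, 40), rep(c("x", "y"), 20))$gap, 0)
  expect_true(is.na(fairness_gaps(rep(1, 40), rep("x", 40))$gap))
})

test_that("fairness gap vanishes when subgroups are independent of difficulty", {
  co <- test_cohort()
  pat <- co$manifest[!duplicated(co$manifest$patient_id), ]
  set.seed(5)
  correct <- rbinom(nrow(pat), 1, 0.9)  # difficulty independent of subgroup
  fr <- fairness_gaps(correct, pat$sex, min_group_size = 10L)
  expect_lt(fr$gap, 0.15)
})

test_that("attention efficiency against the relevance reference", {
  rel <- rep(c(1, 0), each = 50)
  att_perfect <- rel + runif(100, 0, 0.1)
  expect_equal(attention_efficiency(att_perfect, rel, P = 0.6), 1)
  att_anti <- 1 - rel + runif(100, 0, 0.1)
  expect_equal(attention_efficiency(att_anti, rel, P = 0.6), 0)
  # permutation null: efficiency ~ prevalence
  set.seed(6)
  effs <- replicate(200, attention_efficiency(runif(100), rel, P = 0.5))
  expect_equal(mean(effs), 0.5, tolerance = 0.03)
  expect_error(attention_efficiency(rep(0, 10), rep(1, 10), P = 0.5), "zero")
})
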