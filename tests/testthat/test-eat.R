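# Ambiguity scoring, cluster selection, and elimination of ambiguous tiles.

test_that("ambiguity score is 1 minus the absolute probability margin", {
  expect_equal(ambiguity_score(c(1, 0)), 0)
  expect_equal(ambiguity_score(c(0.5, 0.5)), 1)
  expect_equal(ambiguity_score(c(0.8, 0.2)), 0.4)
  expect_error(ambiguity_score(c(0.3, 0.3, 0.4)), "binary")
})

test_that("silhouette selection recovers the generating cluster count", {
  set.seed(2)
  X <- rbind(matrix(rnorm(400, -4, 0.5), 200, 2),
             matrix(rnorm(400, 4, 0.5), 200, 2),
             cbind(rnorm(200, 0, 0.5), rnorm(200, 6, 0.5)))
  k <- select_k(X, k_range = 2:6, seed = 3L)
  expect_equal(as.integer(k), 3L)
  # deterministic under a fixed seed, even on structureless data
  X1 <- matrix(rnorm(400), 200, 2)
  expect_equal(as.vector(select_k(X1, seed = 5L)), as.vector(select_k(X1, seed = 5L)))
  expect_error(select_k(matrix(1, 50, 2), seed = 1L), "degenerate")
})

test_that("k-means recovers generator centroids on a large cohort", {
  # well-separated geometry so the k-means partition matches the generator's
  means <- matrix(0, 3, 8)
  means[1, 1] <- -4; means[2, 1] <- 4; means[3, 2] <- 5
  cfg <- cohort_config(n_patients_per_class = 70L, tiles_per_slide = c(70L, 80L),
                       cluster_means = means, seed = 11L)
  co <- generate_cohort(cfg)
  cl <- fit_clusters(co$embeddings, k = 3L, seed = 2L)
  # match each recovered center to its nearest configured centroid
  d <- as.matrix(dist(rbind(cl$centers, cfg$cluster_means)))[1:3, 4:6]
  expect_true(all(apply(d, 1L, min) < 0.1))
  expect_equal(sort(unname(apply(d, 1L, which.min))), 1:3)  # one-to-one
  # exact recovery from true centers at zero scale
  cfg0 <- cohort_config(n_patients_per_class = 4L, cluster_scales = c(0, 0, 0),
                        ambiguous_fraction = 0.3, seed = 3L)
  co0 <- generate_cohort(cfg0)
  cl0 <- fit_clusters(co0$embeddings, k = 3L, seed = 1L,
                      centers = cfg0$cluster_means)
  expect_equal(unname(cl0$centers[order(cl0$centers[, 1]), ]),
               unname(cfg0$cluster_means[order(cfg0$cluster_means[, 1]), ]))
  expect_error(fit_clusters(matrix(rnorm(8), 4, 2), k = 10L), "exceeds")
})

test_that("clusters without label dominance are flagged, with higher ambiguity", {
  assign <- rep(1:3, each = 100)
  labels <- c(rep(0L, 100), rep(1L, 100), rep(c(0L, 1L), 50))
  amb <- c(runif(200, 0, 0.3), runif(100, 0.7, 1))
  flag <- identify_ambiguous(assign, labels, dominance_threshold = 0.7,
                             ambiguity = amb)
  expect_equal(flag$ambiguous_ids, 3L)
  expect_gt(flag$mean_ambiguity["3"], max(flag$mean_ambiguity[c("1", "2")]))
  # fully dominated cluster is never flagged
  expect_length(identify_ambiguous(rep(1:2, each = 50),
                                   rep(c(0L, 1L), each = 50), 0.7)$ambiguous_ids, 0L)
})

test_that("exactly one of three clusters is ambiguous and its tiles are removed", {
  co <- test_cohort()
  idx <- ambiguity_index("cluster", embeddings = co$embeddings,
                         labels = co$manifest$label, k = 3L, seed = 2L)
  expect_length(idx$ambiguous_ids, 1L)
  # with the default overlapping geometry, boundary tiles blur the fraction
  el <- eliminate(co, idx)
  expect_equal(el$removed_fraction, 2 / 3, tolerance = 0.15)
  removed <- co$manifest$source_cluster[!el$report$kept]
  expect_gt(mean(removed == 3L), 0.9)
  # with well-separated clusters the removed fraction matches the generator
  means <- 2 * cohort_config()$cluster_means
  cfg <- cohort_config(cluster_means = means, seed = 55L)
  co2 <- generate_cohort(cfg)
  idx2 <- ambiguity_index("cluster", embeddings = co2$embeddings,
                          labels = co2$manifest$label, k = 3L, seed = 2L)
  el2 <- eliminate(co2, idx2)
  expect_length(idx2$ambiguous_ids, 1L)
  expect_equal(el2$removed_fraction, 2 / 3, tolerance = 0.02)
})

test_that("elimination modes honor their contracts and are idempotent", {
  co <- test_cohort()
  # retain_rate = 1 is the identity
  id1 <- ambiguity_index("random", retain_rate = 1, seed = 1L)
  expect_equal(eliminate(co, id1)$tiles$manifest, co$manifest)
  # threshold mode keeps the lowest-ambiguity fraction and is idempotent
  scores <- ambiguity_score(proxy_tile_probs(co))
  thr <- ambiguity_index("threshold", scores = scores, retain_rate = 0.4)
  el1 <- eliminate(co, thr, scores = scores)
  expect_equal(1 - el1$removed_fraction, 0.4, tolerance = 0.01)
  kept_scores <- scores[el1$report$kept]
  expect_lte(max(kept_scores), min(scores[!el1$report$kept]))
  el2 <- eliminate(el1$tiles, thr, scores = kept_scores)
  expect_equal(el2$tiles$manifest, el1$tiles$manifest)
  # random mode is idempotent too (per-tile seeded decision)
  rnd <- ambiguity_index("random", retain_rate = 0.5, seed = 3L)
  r1 <- suppressWarnings(eliminate(co, rnd))
  r2 <- suppressWarnings(eliminate(r1$tiles, rnd))
  expect_equal(r2$tiles$manifest, r1$tiles$manifest)
  expect_equal(1 - r1$removed_fraction, 0.5, tolerance = 0.05)
  # cluster mode: idempotent and warns when slides empty out
  cidx <- ambiguity_index("cluster", embeddings = co$embeddings,
                          labels = co$manifest$label, k = 3L, seed = 2L)
  c1 <- eliminate(co, cidx)
  c2 <- eliminate(c1$tiles, cidx)
  expect_equal(c2$tiles$manifest, c1$tiles$manifest)
  all_amb <- tile_subset(co, co$manifest$source_cluster == 3L)
  expect_warning(eliminate(all_amb, cidx), "no informative tiles")
})

test_that("invalid index configurations error", {
  expect_error(ambiguity_index("random", retain_rate = 0), "retain_rate")
  expect_error(ambiguity_index("threshold"), "scores")
})
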