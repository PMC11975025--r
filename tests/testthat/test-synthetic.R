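# Synthetic cohort generator: hierarchy, determinism, cluster geometry.

test_that("cohort respects label balance and hierarchy integrity", {
  co <- test_cohort()
  m <- co$manifest
  # patients per class exact
  pat <- m[!duplicated(m$patient_id), ]
  expect_equal(as.vector(table(pat$label)), c(50L, 50L))
  # every tile maps to one slide, every slide to one patient
  expect_true(all(table(unique(m[, c("slide_id", "patient_id")])$slide_id) == 1L))
  expect_equal(sum(table(m$slide_id)), nrow(m))
  # all tiles of a slide share the weak label
  expect_true(all(tapply(m$label, m$slide_id, function(x) length(unique(x))) == 1L))
  # tiles per slide within configured range
  expect_true(all(table(m$slide_id) >= 20 & table(m$slide_id) <= 40))
})

test_that("identical (config, seed) reproduces identical cohorts", {
  cfg <- cohort_config(n_patients_per_class = 10L, seed = 7L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_ood_cohort(cfg, 5L), generate_ood_cohort(cfg, 5L))
})

test_that("zero cluster scale collapses tiles onto the centroid", {
  cfg <- cohort_config(n_patients_per_class = 4L, cluster_scales = c(0, 0, 0),
                       tiles_per_slide = c(5L, 5L), seed = 3L)
  co <- generate_cohort(cfg)
  for (k in 1:3) {
    idx <- co$manifest$source_cluster == k
    if (any(idx)) {
      expect_equal(unname(co$embeddings[idx, , drop = FALSE]),
                   matrix(cfg$cluster_means[k, ], sum(idx), cfg$embed_dim,
                          byrow = TRUE))
    }
  }
})

test_that("empirical cluster means match configuration at Monte-Carlo accuracy", {
  cfg <- cohort_config(n_patients_per_class = 70L, tiles_per_slide = c(70L, 80L),
                       seed = 11L)
  co <- generate_cohort(cfg)   # ~10,500 tiles
  for (k in 1:3) {
    idx <- co$manifest$source_cluster == k
    n_k <- sum(idx)
    emp <- colMeans(co$embeddings[idx, , drop = FALSE])
    tol <- 4 * cfg$cluster_scales[k] / sqrt(n_k)
    expect_true(all(abs(emp - cfg$cluster_means[k, ]) < tol),
                info = sprintf("cluster %d mean off by > 4*scale/sqrt(n)", k))
  }
})

test_that("OOD cohort is displaced from every In-D centroid", {
  cfg <- cohort_config(n_patients_per_class = 20L, ood_mean_shift = 10,
                       seed = 5L)
  oo <- generate_ood_cohort(cfg, 20L)
  expect_true(all(oo$manifest$is_ood))
  for (k in sort(unique(oo$manifest$source_cluster))) {
    emp <- colMeans(oo$embeddings[oo$manifest$source_cluster == k, , drop = FALSE])
    dmin <- min(sqrt(rowSums(sweep(cfg$cluster_means, 2L, emp)^2)))
    expect_gte(dmin, 10 - 0.5)
  }
})

test_that("OOD edge cases: zero shift warns, zero patients gives empty table", {
  cfg0 <- cohort_config(ood_mean_shift = 0, seed = 2L)
  expect_warning(generate_ood_cohort(cfg0, 2L), "indistinguishable")
  expect_equal(n_tiles(suppressWarnings(generate_ood_cohort(cfg0, 0L))), 0L)
})

test_that("nearest-centroid classifier separates In-D from far OOD perfectly", {
  cfg <- cohort_config(n_patients_per_class = 10L, ood_mean_shift = 10, seed = 9L)
  co <- generate_cohort(cfg)
  oo <- generate_ood_cohort(cfg, 10L)
  ood_ctr <- wsitrust:::ood_centers(cfg)
  all_ctr <- rbind(cfg$cluster_means, ood_ctr)
  assign_ind <- wsitrust:::nearest_center(co$embeddings, all_ctr)
  assign_ood <- wsitrust:::nearest_center(oo$embeddings, all_ctr)
  expect_true(all(assign_ind <= 3L))
  expect_true(all(assign_ood > 3L))
})

test_that("relevance mask flags exactly the class-dominant clusters", {
  co_sep <- sep_cohort()
  expect_true(all(relevance_mask(co_sep) == 1L))
  cfg_amb <- cohort_config(n_patients_per_class = 5L, ambiguous_fraction = 1,
                           seed = 4L)
  expect_true(all(relevance_mask(generate_cohort(cfg_amb)) == 0L))
  co <- test_cohort()
  expect_equal(mean(relevance_mask(co)), 1 - 2 / 3, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(ambiguous_fraction = 1.2), "ambiguous_fraction")
  expect_error(cohort_config(embed_dim = 1L), "embed_dim")
  expect_error(cohort_config(cluster_scales = c(1, -1, 1)), "cluster_scales")
  expect_error(cohort_config(tiles_per_slide = c(10L, 5L)), "tiles_per_slide")
})
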