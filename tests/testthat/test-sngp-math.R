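# Mathematical contracts of the SNGP building blocks: spectral
# normalization, the RFF kernel approximation, the GP head posterior.

test_that("spectral normalization follows the cap-or-pass rule", {
  W <- diag(c(2, 0.5))
  res <- spectral_normalize(W, c = 1)
  expect_equal(res$lambda, 2, tolerance = 1e-8)
  expect_equal(res$weight, diag(c(1, 0.25)), tolerance = 1e-8)
  # matrix already inside the ball passes through unchanged
  W2 <- diag(c(0.6, 0.3))
  expect_equal(spectral_normalize(W2, c = 1)$weight, W2)
  expect_warning(res0 <- spectral_normalize(matrix(0, 3, 3), c = 1), "zero")
  expect_equal(res0$lambda, 0)
})

test_that("power iteration matches exact SVD on random matrices", {
  set.seed(42)
  for (i in 1:5) {
    W <- matrix(rnorm(64), 8, 8)
    res <- spectral_normalize(W, c = 1e9, n_iter = 50L)
    expect_equal(res$lambda, svd(W, nu = 0, nv = 0)$d[1], tolerance = 1e-6)
  }
})

test_that("RFF features have unit self-kernel on average", {
  set.seed(1)
  vals <- vapply(1:20, function(i) {
    head <- rff_head(6L, D = 512L, seed = i)
    h <- rnorm(6)
    sum(rff_features(h, head)^2)
  }, numeric(1))
  expect_equal(mean(vals), 1, tolerance = 3 / sqrt(512))
})

test_that("RFF Gram matrix approximates the RBF kernel, error ~ 1/sqrt(D)", {
  set.seed(2)
  H <- matrix(rnorm(12 * 4), 12, 4)
  Ktrue <- exp(-as.matrix(dist(H))^2 / 2)
  errs <- vapply(c(256L, 1024L, 4096L), function(D) {
    head <- rff_head(4L, D = D, seed = 3L)
    phi <- rff_features(H, head)
    mean(abs(tcrossprod(phi) - Ktrue))
  }, numeric(1))
  head4096 <- rff_head(4L, D = 4096L, seed = 3L)
  phi <- rff_features(H, head4096)
  expect_lt(max(abs(tcrossprod(phi) - Ktrue)), 0.05)
  expect_true(all(diff(errs) < 0))          # shrinking with D
  expect_gt(errs[1] / errs[3], 2)           # roughly sqrt(4096/256) = 4
})

test_that("feature norm is invariant to relabeling the RFF coordinates", {
  head <- rff_head(5L, D = 64L, seed = 9L)
  h <- rnorm(5)
  phi <- rff_features(h, head)
  perm <- sample(64L)
  head2 <- head
  head2$W <- head$W[perm, ]; head2$b <- head$b[perm]
  expect_equal(sqrt(sum(rff_features(h, head2)^2)), sqrt(sum(phi^2)))
})

test_that("unfitted head has tau*I precision and unit uncertainty everywhere", {
  head <- rff_head(4L, D = 256L, tau = 2, seed = 5L)
  expect_equal(head$precision, diag(2, 256L))
  phi <- rff_features(matrix(rnorm(20), 5, 4), head)
  po <- predict(head, phi, n_mc_softmax = 0L)
  # uncertainty = phi' phi ~ k(x,x) = 1 in the no-data limit
  expect_equal(po$uncertainty, rep(1, 5), tolerance = 3 / sqrt(256))
  expect_equal(rowSums(po$probs), rep(1, 5), tolerance = 1e-6)
})

test_that("head fit matches an independent Newton solver on a toy problem", {
  set.seed(10)
  n <- 50L; D <- 16L
  phi <- matrix(rnorm(n * D, sd = 0.5), n, D)
  y <- rbinom(n, 1L, plogis(phi %*% rnorm(D)))
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  head <- rff_head(4L, D = D, K = 2L, tau = 1, seed = 1L)
  fitted <- fit_head(phi, y, head)
  # independent oracle: full Newton iteration on the same MAP objective
  Y <- diag(2)[y + 1L, ]
  beta <- rep(0, 2L * D)
  for (it in 1:60) {
    B <- matrix(beta, D)
    p <- wsitrust:::softmax_rows(phi %*% B)
    g <- as.vector(crossprod(phi, p - Y) + B)
    Hm <- matrix(0, 2L * D, 2L * D)
    for (i in seq_len(n)) {
      S <- diag(p[i, ]) - tcrossprod(p[i, ])
      Hm <- Hm + kronecker(S, tcrossprod(phi[i, ]))
    }
    Hm <- Hm + diag(2L * D)
    # kronecker(S, phi phi') blocks are class-major, matching as.vector(B)
    beta <- beta - solve(Hm, g)
  }
  expect_equal(as.vector(fitted$beta), beta, tolerance = 1e-3)
  # perfect training accuracy on a separable design
  phi_sep <- rbind(matrix(rnorm(40, -2, 0.1), 20, 2),
                   matrix(rnorm(40, 2, 0.1), 20, 2))
  head2 <- rff_head(4L, D = 2L, K = 2L, seed = 2L)
  f2 <- fit_head(phi_sep, rep(c(0L, 1L), each = 20L), head2)
  expect_equal(mean(max.col(phi_sep %*% f2$beta) - 1L == rep(c(0L, 1L), each = 20L)), 1)
  expect_error(fit_head(phi_sep, rep(0L, 40L), head2), "single class")
})

test_that("adding training data at the query point shrinks uncertainty", {
  head <- rff_head(3L, D = 64L, tau = 1, seed = 8L)
  hstar <- c(1, -1, 0.5)
  phi_star <- rff_features(hstar, head)
  u0 <- predict(head, phi_star, n_mc_softmax = 0L)$uncertainty
  # accumulate 100 tiles exactly at h*
  head$precision <- head$precision + 100 * crossprod(phi_star)
  u1 <- predict(head, phi_star, n_mc_softmax = 0L)$uncertainty
  expect_lt(u1, u0)
  # single-tile update agrees with the Sherman-Morrison closed form
  head2 <- rff_head(3L, D = 64L, tau = 1, seed = 8L)
  P0 <- diag(1, 64L)
  v <- as.vector(phi_star)
  u_sm <- 1 * (sum(v * v) - (sum(v * v))^2 / (1 + sum(v * v)))
  head2$precision <- head2$precision + crossprod(phi_star)
  expect_equal(predict(head2, phi_star, n_mc_softmax = 0L)$uncertainty,
               u_sm, tolerance = 1e-8)
})

test_that("predictive variance grows with distance from the training cloud", {
  set.seed(3)
  head <- rff_head(2L, D = 512L, tau = 1, seed = 4L)
  Htr <- matrix(rnorm(200 * 2, sd = 0.3), 200, 2)
  head$precision <- crossprod(rff_features(Htr, head)) + diag(1, 512L)
  ray <- seq(0, 4, by = 0.5)
  u <- vapply(ray, function(t) {
    predict(head, rff_features(c(t, 0), head), n_mc_softmax = 0L)$uncertainty
  }, numeric(1))
  # monotone up to finite-D RFF noise, which is largest near saturation (~1)
  expect_true(all(diff(u) > -0.08))
  expect_lt(u[1], 0.1)               # low variance inside the training cloud
  expect_gt(u[length(u)], 0.9)       # saturates at the prior far away
})

test_that("zero predictive variance reduces the softmax integral to softmax(mu)", {
  head <- rff_head(2L, D = 8L, seed = 6L)
  head$beta <- matrix(rnorm(16), 8, 2)
  head$precision <- diag(1e12, 8L)   # sigma^2 -> 0
  phi <- rff_features(matrix(rnorm(10), 5, 2), head)
  po <- predict(head, phi, n_mc_softmax = 200L)
  expect_equal(po$probs, wsitrust:::softmax_rows(phi %*% head$beta),
               tolerance = 1e-5)
})
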