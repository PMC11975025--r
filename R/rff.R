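# Random-Fourier-feature Gaussian-process output layer.
#
# The RFF map phi(h) = sqrt(2/D) cos(-W h + b), with W ~ N(0,1) and
# b ~ U(0, 2pi) fixed at construction, gives a low-rank Monte-Carlo
# approximation to the unit-bandwidth RBF kernel
# k(h, h') = exp(-||h - h'||^2 / 2): E[phi(h).phi(h')] = k(h, h').
# A Bayesian linear model on phi then approximates a GP with that kernel,
# yielding closed-form distance-aware predictive variance from one forward
# pass.

#' Construct a random-Fourier-feature GP head
#'
#' The projection `W` (D x feature_dim, standard normal) and phase `b`
#' (uniform on (0, 2*pi)) are drawn once and immutable thereafter; the
#' coefficients `beta` are the only learnable parameters. Before any data is
#' accumulated the ridge precision is `tau * I`, so predictive uncertainty is
#' `phi' phi ~ 1` everywhere — maximal, as a GP prior should be.
#'
#' @param feature_dim dimension of the latent inputs `h`.
#' @param D RFF dimension (rank of the kernel approximation).
#' @param K number of classes.
#' @param tau positive ridge factor of the precision `Phi'Phi + tau I`.
#' @param seed integer seed for the fixed random projection.
#' @return an object of class `rff_head`.
#' @export
rff_head <- function(feature_dim, D = 1024L, K = 2L, tau = 1, seed = 1L) {
  stopifnot(D >= 1, tau > 0, K >= 2)
  with_stream(seed, "rff-head", {
    W <- matrix(stats::rnorm(D * feature_dim), D, feature_dim)
    b <- stats::runif(D, 0, 2 * pi)
    structure(list(
      W = W, b = b, D = as.integer(D), feature_dim = as.integer(feature_dim),
      K = as.integer(K), tau = tau,
      beta = matrix(0, D, K),
      precision = diag(tau, D),
      fitted = FALSE
    ), class = "rff_head")
  })
}

#' Random Fourier features of latent vectors
#'
#' @param h latent vector or n x feature_dim matrix.
#' @param head an [rff_head()].
#' @return n x D feature matrix `sqrt(2/D) * cos(-W h + b)`.
#' @export
rff_features <- function(h, head) {
  if (is.null(dim(h))) h <- matrix(h, 1L)
  if (ncol(h) != head$feature_dim)
    stop(sprintf("latent dimension %d does not match head feature_dim %d",
                 ncol(h), head$feature_dim), call. = FALSE)
  sqrt(2 / head$D) * cos(-tcrossprod(h, head$W) +
                           matrix(head$b, nrow(h), head$D, byrow = TRUE))
}

head_objective <- function(beta_vec, phi, Y, weight_decay) {
  n <- nrow(phi)
  beta <- matrix(beta_vec, ncol(phi))
  p <- softmax_rows(phi %*% beta)
  ce <- -sum(Y * log(pmax(p, 1e-12)))
  (ce + 0.5 * weight_decay * sum(beta^2)) / n
}

head_gradient <- function(beta_vec, phi, Y, weight_decay) {
  n <- nrow(phi)
  beta <- matrix(beta_vec, ncol(phi))
  p <- softmax_rows(phi %*% beta)
  g <- crossprod(phi, p - Y) + weight_decay * beta
  as.vector(g) / n
}

#' Fit the GP-head coefficients on precomputed RFF features
#'
#' Maximum a posteriori estimate of `beta` under a standard-normal prior
#' (weight decay 1): gradient-based minimization of total cross-entropy plus
#' `||beta||^2 / 2`. The ridge precision `Phi'Phi + tau I` is accumulated
#' exactly over the training rows.
#'
#' @param phi n x D feature matrix from [rff_features()].
#' @param labels integer class labels in `0..K-1`.
#' @param head an [rff_head()] (provides tau and K).
#' @param weight_decay prior precision on beta (default 1, standard normal).
#' @param maxit optimizer iteration cap.
#' @return the fitted `rff_head`.
#' @export
fit_head <- function(phi, labels, head, weight_decay = 1, maxit = 500L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("degenerate fit: labels contain a single class", call. = FALSE)
  stopifnot(nrow(phi) == length(labels), ncol(phi) == head$D)
  Y <- diag(head$K)[labels + 1L, , drop = FALSE]
  opt <- stats::optim(
    par = as.vector(head$beta), fn = head_objective, gr = head_gradient,
    phi = phi, Y = Y, weight_decay = weight_decay,
    method = "L-BFGS-B", control = list(maxit = maxit, factr = 1e4)
  )
  head$beta <- matrix(opt$par, head$D, head$K)
  head$precision <- crossprod(phi) + diag(head$tau, head$D)
  head$fitted <- TRUE
  head
}

precision_inverse <- function(head) {
  ch <- tryCatch(chol(head$precision), error = function(e)
    stop("precision matrix is not positive definite (condition failure in the ",
         "GP head): ", conditionMessage(e), call. = FALSE))
  chol2inv(ch)
}

#' Predictive output of the GP head
#'
#' Computes per-class logit means `mu = phi' beta`, predictive variances
#' `sigma^2 = tau * phi' (Phi'Phi + tau I)^{-1} phi` (the ridge-factor
#' variance, shared across logits), class probabilities as the Gaussian
#' average of the softmax, and the scalar distance-aware uncertainty (equal
#' to the ridge variance).
#'
#' @param object a (fitted) `rff_head`.
#' @param phi n x D feature matrix of query points.
#' @param n_mc_softmax Gaussian logit samples for the softmax integral;
#'   0 selects the mean-field approximation (logits scaled by
#'   `1/sqrt(1 + pi/8 * sigma^2)`).
#' @param seed seed for the Monte-Carlo softmax draws.
#' @param ... unused.
#' @return a `predictive_output`: list with `mu`, `sigma2` (n x K), `probs`
#'   (n x K, rows sum to 1) and `uncertainty` (length-n vector).
#' @export
predict.rff_head <- function(object, phi, n_mc_softmax = 100L, seed = 1L, ...) {
  stopifnot(ncol(phi) == object$D)
  mu <- phi %*% object$beta
  Pinv <- precision_inverse(object)
  u <- object$tau * rowSums((phi %*% Pinv) * phi)
  u <- pmax(u, 0)
  sigma2 <- matrix(u, nrow(phi), object$K)
  probs <- gaussian_softmax(mu, sigma2, n_mc_softmax, seed)
  structure(list(mu = mu, sigma2 = sigma2, probs = probs, uncertainty = u),
            class = "predictive_output")
}

gaussian_softmax <- function(mu, sigma2, n_mc_softmax, seed = 1L) {
  if (n_mc_softmax == 0L) {
    return(softmax_rows(mu / sqrt(1 + (pi / 8) * sigma2)))
  }
  sd <- sqrt(sigma2)
  with_stream(seed, "mc-softmax", {
    acc <- matrix(0, nrow(mu), ncol(mu))
    for (i in seq_len(n_mc_softmax)) {
      z <- mu + matrix(stats::rnorm(length(mu)), nrow(mu)) * sd
      acc <- acc + softmax_rows(z)
    }
    acc / n_mc_softmax
  })
}

#' @export
print.predictive_output <- function(x, ...) {
  cat(sprintf("Predictive output: %d units, %d classes; mean uncertainty %.4f\n",
              nrow(x$probs), ncol(x$probs), mean(x$uncertainty)))
  invisible(x)
}
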