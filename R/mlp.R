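# Internal feed-forward engine: ReLU MLP with optional spectral-normalized
# layers, inverted dropout, and an RFF-GP or dense softmax head. Written in
# base R matrix operations; at desk scale (thousands of tiles, dimensions in
# the tens) BLAS-backed matmuls dominate and the training loop is cheap.
#
# Layers whose input and output widths match are residual blocks
# h + ReLU(hW + b): the identity path preserves a positive lower Lipschitz
# bound while spectral normalization of W caps the upper bound, which is
# what makes the extractor approximately distance-preserving (bi-Lipschitz)
# rather than merely smooth.

mlp_init <- function(d_in, hidden, K, head_type = c("rff", "dense"),
                     D = 1024L, tau = 1, seed = 1L) {
  head_type <- match.arg(head_type)
  with_stream(seed, "mlp-init", {
    dims <- c(d_in, hidden)
    W <- b <- sn <- vector("list", length(hidden))
    for (l in seq_along(hidden)) {
      # He initialization for ReLU layers
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
      sn[[l]] <- spectral_state(W[[l]])
    }
    net <- list(W = W, b = b, sn = sn, d_in = d_in, hidden = hidden, K = K,
                head_type = head_type,
                n_forward = new.env(parent = emptyenv()))
    net$n_forward$count <- 0L
    if (head_type == "rff") {
      net$head <- rff_head(utils::tail(dims, 1L), D = D, K = K, tau = tau,
                           seed = stream_seed(seed, "head"))
    } else {
      d_last <- utils::tail(dims, 1L)
      net$W_out <- matrix(stats::rnorm(d_last * K, sd = sqrt(1 / d_last)), d_last, K)
      net$b_out <- numeric(K)
    }
    net
  })
}

# Forward pass; caches activations for backprop. Dropout masks are sampled
# from the current RNG state when rates > 0 and `dropout` is TRUE.
mlp_forward <- function(net, X, dropout = FALSE, dropout_rates = NULL) {
  net$n_forward$count <- net$n_forward$count + 1L
  H <- X
  caches <- vector("list", length(net$W))
  for (l in seq_along(net$W)) {
    residual <- ncol(net$W[[l]]) == nrow(net$W[[l]])
    A <- sweep(H %*% net$W[[l]], 2L, net$b[[l]], `+`)
    Z <- relu(A)
    mask <- NULL
    rate <- if (dropout && !is.null(dropout_rates)) dropout_rates[l] else 0
    if (isTRUE(rate > 0)) {
      mask <- matrix(stats::rbinom(length(Z), 1L, 1 - rate), nrow(Z)) / (1 - rate)
      Z <- Z * mask
    }
    caches[[l]] <- list(H_in = H, A = A, mask = mask, residual = residual)
    H <- if (residual) H + Z else Z
  }
  if (net$head_type == "rff") {
    U <- -tcrossprod(H, net$head$W) +
      matrix(net$head$b, nrow(H), net$head$D, byrow = TRUE)
    phi <- sqrt(2 / net$head$D) * cos(U)
    logits <- phi %*% net$head$beta
    list(latent = H, phi = phi, U = U, logits = logits, caches = caches)
  } else {
    logits <- sweep(H %*% net$W_out, 2L, net$b_out, `+`)
    list(latent = H, logits = logits, caches = caches)
  }
}

# Backprop from dL/dlogits (n x K, already averaged over the batch).
# Returns gradients for layer weights plus head parameters.
mlp_backward <- function(net, fw, dlogits) {
  grads <- list(W = vector("list", length(net$W)),
                b = vector("list", length(net$W)))
  if (net$head_type == "rff") {
    grads$beta <- crossprod(fw$phi, dlogits)
    dphi <- tcrossprod(dlogits, net$head$beta)
    # phi = sqrt(2/D) cos(U), U = -W h + b  =>  dL/dh = (dphi * s) %*% W
    dH <- (dphi * (sqrt(2 / net$head$D) * sin(fw$U))) %*% net$head$W
  } else {
    grads$W_out <- crossprod(fw$latent, dlogits)
    grads$b_out <- colSums(dlogits)
    dH <- tcrossprod(dlogits, net$W_out)
  }
  for (l in rev(seq_along(net$W))) {
    cache <- fw$caches[[l]]
    dZ <- if (!is.null(cache$mask)) dH * cache$mask else dH
    dA <- dZ * (cache$A > 0)
    grads$W[[l]] <- crossprod(cache$H_in, dA)
    grads$b[[l]] <- colSums(dA)
    dH <- tcrossprod(dA, net$W[[l]]) + if (cache$residual) dH else 0
  }
  grads
}

adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s), t = 0L))
}

adam_update <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  # decoupled (AdamW-style) weight decay
  par <- par - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * par)
  list(par = par, state = st)
}

# Project every hidden layer onto the spectral-norm ball of radius c,
# using one power iteration with the layer's persistent state.
mlp_spectral_project <- function(net, c_bound, n_iter = 1L) {
  for (l in seq_along(net$W)) {
    res <- spectral_normalize(net$W[[l]], c = c_bound, state = net$sn[[l]],
                              n_iter = n_iter)
    net$W[[l]] <- res$weight
    net$sn[[l]] <- res$state
  }
  net
}

# Exact final projection: guarantees ||W||_2 <= c to numerical precision.
mlp_spectral_project_exact <- function(net, c_bound) {
  for (l in seq_along(net$W)) {
    s <- svd(net$W[[l]], nu = 0L, nv = 0L)$d[1L]
    if (s > c_bound) net$W[[l]] <- c_bound * net$W[[l]] / s
  }
  net
}

cross_entropy <- function(probs, Y) {
  -mean(rowSums(Y * log(pmax(probs, 1e-12))))
}
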