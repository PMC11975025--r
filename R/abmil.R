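# Attention-based multiple-instance bag classifier with a spectral-normalized
# embedding trunk and an RFF-GP head. Each slide is a bag of tile embeddings;
# the model learns per-tile attention weights, pools the attended embedding,
# and classifies the bag, so no tile-level labels are needed beyond the weak
# slide label.

#' ABMIL model configuration
#'
#' Defaults follow common ABMIL practice for weakly supervised slide
#' classification: dropout 0.1 on the input features and 0.25 after each
#' intermediate layer, AdamW with a cosine learning-rate schedule starting
#' at 1e-4, at most 20 epochs, cross-entropy loss. Hidden sizes are
#' desk-scale (the architecture is width-agnostic).
#'
#' @param hidden_sizes widths of the two fully-connected embedding layers.
#' @param attention_dim width of the tanh attention layer.
#' @param dropout_in dropout rate on the input features.
#' @param dropout_hidden dropout rate after each intermediate layer.
#' @param epochs maximum training epochs.
#' @param lr initial AdamW learning rate (cosine-annealed to 0).
#' @param weight_decay decoupled weight decay.
#' @param c spectral-norm bound applied to all fully-connected layers.
#' @param D,tau RFF dimension and ridge factor of the GP head.
#' @param n_mc_softmax Gaussian logit samples for the softmax integral.
#' @param val_fraction patient-level validation fraction.
#' @param spectral_norm logical; disable for the unnormalized twin.
#' @param seed integer seed.
#' @return an object of class `abmil_config`.
#' @export
abmil_config <- function(hidden_sizes = c(64L, 48L), attention_dim = 16L,
                         dropout_in = 0.1, dropout_hidden = 0.25,
                         epochs = 20L, lr = 1e-4, weight_decay = 1e-4,
                         c = 1, D = 256L, tau = 1, n_mc_softmax = 100L,
                         val_fraction = 0.15, spectral_norm = TRUE, seed = 1L) {
  stopifnot(length(hidden_sizes) == 2L, c > 0, tau > 0)
  structure(as.list(environment()), class = "abmil_config")
}

make_bags <- function(tiles) {
  m <- tiles$manifest
  sids <- unique(m$slide_id)
  lapply(sids, function(s) {
    idx <- which(m$slide_id == s)
    list(slide_id = s, patient_id = m$patient_id[idx[1]],
         label = m$label[idx[1]], idx = idx,
         X = tiles$embeddings[idx, , drop = FALSE])
  })
}

abmil_forward <- function(par, bag_X, cfg, dropout = FALSE) {
  H <- bag_X
  masks <- list(NULL, NULL, NULL)
  if (dropout && cfg$dropout_in > 0) {
    masks[[1]] <- matrix(stats::rbinom(length(H), 1L, 1 - cfg$dropout_in),
                         nrow(H)) / (1 - cfg$dropout_in)
    H <- H * masks[[1]]
  }
  A1 <- sweep(H %*% par$W1, 2L, par$b1, `+`); E1 <- relu(A1)
  if (dropout && cfg$dropout_hidden > 0) {
    masks[[2]] <- matrix(stats::rbinom(length(E1), 1L, 1 - cfg$dropout_hidden),
                         nrow(E1)) / (1 - cfg$dropout_hidden)
    E1 <- E1 * masks[[2]]
  }
  A2 <- sweep(E1 %*% par$W2, 2L, par$b2, `+`); E2 <- relu(A2)
  if (dropout && cfg$dropout_hidden > 0) {
    masks[[3]] <- matrix(stats::rbinom(length(E2), 1L, 1 - cfg$dropout_hidden),
                         nrow(E2)) / (1 - cfg$dropout_hidden)
    E2 <- E2 * masks[[3]]
  }
  Tn <- tanh(E2 %*% par$V)
  s <- drop(Tn %*% par$w)
  a <- exp(s - max(s)); a <- a / sum(a)
  r <- drop(crossprod(E2, a))
  U <- drop(-par$head$W %*% r) + par$head$b
  phi <- sqrt(2 / par$head$D) * cos(U)
  logits <- drop(crossprod(par$head$beta, phi))
  list(H = H, A1 = A1, E1 = E1, A2 = A2, E2 = E2, Tn = Tn, s = s, a = a,
       r = r, U = U, phi = phi, logits = logits, masks = masks)
}

abmil_backward <- function(par, fw, dlogits, cfg) {
  g <- list()
  g$beta <- outer(fw$phi, dlogits)
  dphi <- drop(par$head$beta %*% dlogits)
  dr <- drop(crossprod(par$head$W, dphi * (sqrt(2 / par$head$D) * sin(fw$U))))
  # r = E2' a
  dE2 <- outer(fw$a, dr)
  da <- drop(fw$E2 %*% dr)
  ds <- fw$a * (da - sum(fw$a * da))
  dT <- outer(ds, par$w)
  g$w <- drop(crossprod(fw$Tn, ds))
  dpre <- dT * (1 - fw$Tn^2)
  g$V <- crossprod(fw$E2, dpre)
  dE2 <- dE2 + tcrossprod(dpre, par$V)
  if (!is.null(fw$masks[[3]])) dE2 <- dE2 * fw$masks[[3]]
  dA2 <- dE2 * (fw$A2 > 0)
  g$W2 <- crossprod(fw$E1, dA2); g$b2 <- colSums(dA2)
  dE1 <- tcrossprod(dA2, par$W2)
  if (!is.null(fw$masks[[2]])) dE1 <- dE1 * fw$masks[[2]]
  dA1 <- dE1 * (fw$A1 > 0)
  g$W1 <- crossprod(fw$H, dA1); g$b1 <- colSums(dA1)
  g
}

abmil_project <- function(par, cfg, states, n_iter = 1L) {
  for (nm in c("W1", "W2", "V")) {
    res <- spectral_normalize(par[[nm]], c = cfg$c, state = states[[nm]],
                              n_iter = n_iter)
    par[[nm]] <- res$weight
    states[[nm]] <- res$state
  }
  list(par = par, states = states)
}

#' Fit an attention-based multiple-instance bag classifier
#'
#' Tile embeddings pass through two spectral-normalized fully-connected ReLU
#' layers, a tanh attention layer produces per-tile weights (softmax within
#' each bag, summing to 1), the attention-pooled bag representation feeds an
#' RFF-GP head, and the whole model is trained end-to-end with AdamW, a
#' cosine learning-rate schedule and cross-entropy on the weak slide labels.
#' Zero-tile bags are skipped with a warning.
#'
#' @param tiles a `tile_table`; bags are slides, labels the weak slide labels.
#' @param config an [abmil_config()].
#' @param validation optional `tile_table` used for validation; otherwise a
#'   patient-level fraction is held out.
#' @return an object of class `abmil` with `predict`, `print` methods.
#' @export
abmil <- function(tiles, config = abmil_config(), validation = NULL) {
  stopifnot(inherits(tiles, "tile_table"))
  bags <- make_bags(tiles)
  empty <- vapply(bags, function(b) length(b$idx) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " zero-tile bag(s) skipped")
    bags <- bags[!empty]
  }
  if (length(bags) == 0L) stop("no nonempty bags to train on", call. = FALSE)
  if (is.null(validation)) {
    pats <- unique(vapply(bags, `[[`, character(1), "patient_id"))
    val_p <- with_stream(config$seed, "abmil-val",
                         sample(pats, max(1L, round(config$val_fraction * length(pats)))))
    val <- vapply(bags, function(b) b$patient_id %in% val_p, logical(1))
    tr_bags <- bags[!val]; val_bags <- bags[val]
  } else {
    tr_bags <- bags; val_bags <- make_bags(validation)
  }
  K <- length(unique(vapply(bags, `[[`, numeric(1), "label")))
  if (K < 2L) stop("need at least 2 classes among bag labels", call. = FALSE)
  d <- ncol(tiles$embeddings)
  h <- config$hidden_sizes
  par <- with_stream(config$seed, "abmil-init", list(
    W1 = matrix(stats::rnorm(d * h[1], sd = sqrt(2 / d)), d, h[1]),
    b1 = numeric(h[1]),
    W2 = matrix(stats::rnorm(h[1] * h[2], sd = sqrt(2 / h[1])), h[1], h[2]),
    b2 = numeric(h[2]),
    V = matrix(stats::rnorm(h[2] * config$attention_dim,
                            sd = sqrt(1 / h[2])), h[2], config$attention_dim),
    w = stats::rnorm(config$attention_dim, sd = 0.1),
    head = rff_head(h[2], D = config$D, K = K, tau = config$tau,
                    seed = stream_seed(config$seed, "abmil-head"))
  ))
  par$head$beta <- par$head$beta  # learnable; starts at 0
  states <- list(W1 = spectral_state(par$W1), W2 = spectral_state(par$W2),
                 V = spectral_state(par$V))
  if (config$spectral_norm) {
    pr <- abmil_project(par, config, states, n_iter = 5L)
    par <- pr$par; states <- pr$states
  }
  pnames <- c("W1", "b1", "W2", "b2", "V", "w", "beta")
  getp <- function(nm) if (nm == "beta") par$head$beta else par[[nm]]
  setp <- function(nm, v) if (nm == "beta") par$head$beta <<- v else par[[nm]] <<- v
  opt <- adam_state(lapply(pnames, function(nm) {
    p <- getp(nm); if (is.null(dim(p))) length(p) else dim(p)
  }))
  names(opt) <- pnames
  total_steps <- config$epochs * length(tr_bags)
  step <- 0L
  history <- data.frame(epoch = integer(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, par = NULL)
  val_acc <- function(p) {
    preds <- vapply(val_bags, function(b) {
      fw <- abmil_forward(p, b$X, config, dropout = FALSE)
      which.max(fw$logits) - 1L
    }, numeric(1))
    mean(preds == vapply(val_bags, `[[`, numeric(1), "label"))
  }
  with_stream(config$seed, "abmil-train", {
    for (epoch in seq_len(config$epochs)) {
      for (bi in sample(length(tr_bags))) {
        step <- step + 1L
        lr_t <- config$lr * 0.5 * (1 + cos(pi * (step - 1L) / total_steps))
        b <- tr_bags[[bi]]
        fw <- abmil_forward(par, b$X, config, dropout = TRUE)
        p <- exp(fw$logits - max(fw$logits)); p <- p / sum(p)
        y1 <- numeric(K); y1[b$label + 1L] <- 1
        g <- abmil_backward(par, fw, p - y1, config)
        for (nm in pnames) {
          upd <- adam_update(getp(nm), g[[nm]], opt[[nm]], lr = lr_t,
                             weight_decay = config$weight_decay)
          setp(nm, upd$par)
          opt[[nm]] <- upd$state
        }
        if (config$spectral_norm) {
          pr <- abmil_project(par, config, states, n_iter = 1L)
          par <- pr$par; states <- pr$states
        }
      }
      acc <- val_acc(par)
      history <- rbind(history, data.frame(epoch = epoch, val_accuracy = acc))
      if (acc >= best$acc) { best$acc <- acc; best$par <- par }
    }
  })
  par <- best$par
  if (config$spectral_norm) {
    for (nm in c("W1", "W2", "V")) {
      s <- svd(par[[nm]], nu = 0, nv = 0)$d[1]
      if (s > config$c) par[[nm]] <- config$c * par[[nm]] / s
    }
  }
  reps <- t(vapply(tr_bags, function(b)
    abmil_forward(par, b$X, config, dropout = FALSE)$r, numeric(h[2])))
  Phi <- rff_features(reps, par$head)
  par$head$precision <- crossprod(Phi) + diag(config$tau, config$D)
  par$head$fitted <- TRUE
  structure(list(par = par, config = config, K = K,
                 history = history, val_accuracy = best$acc),
            class = "abmil")
}

#' @rdname abmil
#' @param object a fitted `abmil` model.
#' @param newdata a `tile_table` to score (bags = slides).
#' @param ... unused.
#' @return `predict` returns a list: `slides` (data.frame with slide_id,
#'   patient_id, label), `pred` (a `predictive_output`, one row per slide)
#'   and `attention` (per-tile weights, named by tile_id; weights within a
#'   bag sum to 1).
#' @export
predict.abmil <- function(object, newdata, ...) {
  bags <- make_bags(newdata)
  keep <- vapply(bags, function(b) length(b$idx) > 0L, logical(1))
  if (any(!keep)) warning(sum(!keep), " zero-tile bag(s) skipped at prediction")
  bags <- bags[keep]
  cfg <- object$config
  h2 <- cfg$hidden_sizes[2]
  reps <- matrix(0, length(bags), h2)
  attention <- numeric(0)
  for (i in seq_along(bags)) {
    fw <- abmil_forward(object$par, bags[[i]]$X, cfg, dropout = FALSE)
    reps[i, ] <- fw$r
    a <- fw$a
    names(a) <- newdata$manifest$tile_id[bags[[i]]$idx]
    attention <- c(attention, a)
  }
  Phi <- rff_features(reps, object$par$head)
  po <- predict.rff_head(object$par$head, Phi, n_mc_softmax = cfg$n_mc_softmax,
                         seed = stream_seed(cfg$seed, "abmil-predict"))
  slides <- data.frame(
    slide_id = vapply(bags, `[[`, character(1), "slide_id"),
    patient_id = vapply(bags, `[[`, character(1), "patient_id"),
    label = vapply(bags, `[[`, numeric(1), "label"),
    stringsAsFactors = FALSE
  )
  list(slides = slides, pred = po, attention = attention)
}

#' @export
print.abmil <- function(x, ...) {
  cat(sprintf("ABMIL bag classifier: hidden [%s], attention dim %d, RFF dim %d\n",
              paste(x$config$hidden_sizes, collapse = ", "),
              x$config$attention_dim, x$config$D))
  cat(sprintf("  best validation accuracy %.3f over %d epochs\n",
              x$val_accuracy, nrow(x$history)))
  invisible(x)
}
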