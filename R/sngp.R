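# Spectral-normalized neural Gaussian process tile classifier, plus the
# Monte Carlo dropout baseline.

#' SNGP model configuration
#'
#' @param c spectral-norm bound on every hidden layer (Lipschitz cap).
#' @param n_power_iter power iterations per training step (persistent state).
#' @param D RFF dimension of the GP head.
#' @param tau ridge factor of the GP precision.
#' @param n_mc_softmax Gaussian logit samples for the softmax integral
#'   (0 = mean-field approximation).
#' @param hidden_sizes hidden-layer widths of the MLP extractor. Consecutive
#'   equal widths form residual blocks `h + ReLU(hW + b)`; with spectral
#'   normalization these keep the extractor bi-Lipschitz (the identity path
#'   gives the positive lower bound, the spectral cap the upper bound).
#' @param dropout per-hidden-layer dropout rates (0 disables).
#' @param epochs,batch_size,lr,weight_decay Adam training settings.
#' @param val_fraction patient-level fraction held out for validation when no
#'   explicit validation set is given; the best epoch by validation accuracy
#'   is retained.
#' @param spectral_norm logical; FALSE gives the unnormalized twin used in
#'   bi-Lipschitz comparisons.
#' @param seed integer seed driving initialization, batching and dropout.
#' @return an object of class `sngp_config`.
#' @export
sngp_config <- function(c = 1, n_power_iter = 1L, D = 1024L, tau = 1,
                        n_mc_softmax = 100L, hidden_sizes = c(32L, 32L),
                        dropout = NULL, epochs = 30L, batch_size = 128L,
                        lr = 1e-3, weight_decay = 1e-4, val_fraction = 0.15,
                        spectral_norm = TRUE, seed = 1L) {
  stopifnot(c > 0, D >= 1, tau > 0)
  dropout <- dropout %||% rep(0, length(hidden_sizes))
  structure(as.list(environment()), class = "sngp_config")
}

resolve_xy <- function(x, y) {
  if (inherits(x, "tile_table")) {
    list(X = x$embeddings, y = as.integer(x$manifest$label),
         patient = x$manifest$patient_id)
  } else {
    stopifnot(!is.null(y))
    list(X = as.matrix(x), y = as.integer(y), patient = NULL)
  }
}

split_validation <- function(xy, val_fraction, seed) {
  if (is.null(val_fraction) || val_fraction <= 0)
    stop("no validation split: supply a validation set or a positive val_fraction",
         call. = FALSE)
  with_stream(seed, "val-split", {
    if (!is.null(xy$patient)) {
      pats <- unique(xy$patient)
      val_p <- sample(pats, max(1L, round(val_fraction * length(pats))))
      val_idx <- xy$patient %in% val_p
    } else {
      n <- length(xy$y)
      val_idx <- seq_len(n) %in% sample(n, max(1L, round(val_fraction * n)))
    }
    val_idx
  })
}

train_mlp <- function(X, y, Xval, yval, config, head_type) {
  K <- length(unique(c(y, yval)))
  if (K < 2L) stop("need at least 2 classes to train", call. = FALSE)
  net <- mlp_init(ncol(X), config$hidden_sizes, K, head_type,
                  D = config$D, tau = config$tau, seed = config$seed)
  Y <- diag(K)[y + 1L, , drop = FALSE]
  par_names <- c(paste0("W", seq_along(net$W)), paste0("b", seq_along(net$W)),
                 if (head_type == "rff") "beta" else c("W_out", "b_out"))
  get_par <- function(nm) {
    if (grepl("^W[0-9]", nm)) net$W[[as.integer(sub("W", "", nm))]]
    else if (grepl("^b[0-9]", nm)) net$b[[as.integer(sub("b", "", nm))]]
    else if (nm == "beta") net$head$beta
    else net[[nm]]
  }
  set_par <- function(nm, v) {
    if (grepl("^W[0-9]", nm)) net$W[[as.integer(sub("W", "", nm))]] <<- v
    else if (grepl("^b[0-9]", nm)) net$b[[as.integer(sub("b", "", nm))]] <<- v
    else if (nm == "beta") net$head$beta <<- v
    else net[[nm]] <<- v
  }
  opt <- adam_state(lapply(par_names, function(nm) {
    p <- get_par(nm); if (is.null(dim(p))) length(p) else dim(p)
  }))
  names(opt) <- par_names
  if (config$spectral_norm) net <- mlp_spectral_project(net, config$c, n_iter = 5L)
  history <- data.frame(epoch = integer(0), val_accuracy = numeric(0))
  best <- list(acc = -Inf, net = NULL)
  with_stream(config$seed, "mlp-train", {
    n <- nrow(X)
    use_dropout <- any(config$dropout > 0)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1L, n)]
        fw <- mlp_forward(net, X[bi, , drop = FALSE], dropout = use_dropout,
                          dropout_rates = config$dropout)
        p <- softmax_rows(fw$logits)
        dlogits <- (p - Y[bi, , drop = FALSE]) / length(bi)
        g <- mlp_backward(net, fw, dlogits)
        for (nm in par_names) {
          grad <- if (grepl("^W[0-9]", nm)) g$W[[as.integer(sub("W", "", nm))]]
          else if (grepl("^b[0-9]", nm)) g$b[[as.integer(sub("b", "", nm))]]
          else g[[nm]]
          upd <- adam_update(get_par(nm), grad, opt[[nm]], lr = config$lr,
                             weight_decay = config$weight_decay)
          set_par(nm, upd$par)
          opt[[nm]] <- upd$state
        }
        if (config$spectral_norm)
          net <- mlp_spectral_project(net, config$c, n_iter = config$n_power_iter)
      }
      fv <- mlp_forward(net, Xval)
      acc <- mean(max.col(fv$logits) - 1L == yval)
      history <- rbind(history, data.frame(epoch = epoch, val_accuracy = acc))
      if (acc >= best$acc) {
        best$acc <- acc
        best$net <- net[c("W", "b", if (head_type == "rff") "head" else c("W_out", "b_out"))]
      }
    }
  })
  for (nm in names(best$net)) net[[nm]] <- best$net[[nm]]
  if (config$spectral_norm) net <- mlp_spectral_project_exact(net, config$c)
  list(net = net, history = history, val_accuracy = best$acc)
}

#' Fit a spectral-normalized neural Gaussian process classifier
#'
#' Trains an MLP whose hidden layers are projected onto a spectral-norm ball
#' after every optimizer step (keeping the extractor approximately
#' distance-preserving), with a random-Fourier-feature GP output layer
#' trained end-to-end by cross-entropy. After training, the GP ridge
#' precision is accumulated exactly over the training tiles, giving
#' closed-form distance-aware predictive variance from a single forward
#' pass.
#'
#' @param x a `tile_table` or numeric feature matrix.
#' @param y integer class labels in `0..K-1` (taken from the manifest when
#'   `x` is a `tile_table`).
#' @param config an [sngp_config()].
#' @param validation optional list `list(x, y)` of validation data; when
#'   absent a patient-level fraction `config$val_fraction` is held out.
#' @return an object of class `sngp` with methods `predict`, `print`,
#'   `summary` and `coef`.
#' @export
sngp <- function(x, y = NULL, config = sngp_config(), validation = NULL) {
  xy <- resolve_xy(x, y)
  if (is.null(validation)) {
    val_idx <- split_validation(xy, config$val_fraction, config$seed)
    Xtr <- xy$X[!val_idx, , drop = FALSE]; ytr <- xy$y[!val_idx]
    Xval <- xy$X[val_idx, , drop = FALSE]; yval <- xy$y[val_idx]
  } else {
    Xtr <- xy$X; ytr <- xy$y
    vxy <- resolve_xy(validation$x, validation$y)
    Xval <- vxy$X; yval <- vxy$y
  }
  fit <- train_mlp(Xtr, ytr, Xval, yval, config, "rff")
  net <- fit$net
  # exact precision accumulation at the retained weights
  fw <- mlp_forward(net, Xtr)
  net$head$precision <- crossprod(fw$phi) + diag(net$head$tau, net$head$D)
  net$head$fitted <- TRUE
  structure(list(net = net, config = config, n_train = nrow(Xtr),
                 history = fit$history, val_accuracy = fit$val_accuracy),
            class = "sngp")
}

#' @rdname sngp
#' @param object a fitted `sngp` model.
#' @param newdata `tile_table` or feature matrix to score.
#' @param n_mc_softmax override of the config's softmax-integral samples.
#' @param ... unused.
#' @return `predict` returns a `predictive_output` (logit means, ridge
#'   variances, probabilities, per-tile uncertainty).
#' @export
predict.sngp <- function(object, newdata, n_mc_softmax = NULL, ...) {
  X <- if (inherits(newdata, "tile_table")) newdata$embeddings else as.matrix(newdata)
  fw <- mlp_forward(object$net, X)
  predict.rff_head(object$net$head, fw$phi,
                   n_mc_softmax = n_mc_softmax %||% object$config$n_mc_softmax,
                   seed = stream_seed(object$config$seed, "predict"))
}

#' Latent representations from a fitted extractor
#' @param object a fitted `sngp` (or `dropout_net`) model.
#' @param newdata `tile_table` or feature matrix.
#' @return matrix of penultimate-layer representations.
#' @export
latent_features <- function(object, newdata) {
  X <- if (inherits(newdata, "tile_table")) newdata$embeddings else as.matrix(newdata)
  mlp_forward(object$net, X)$latent
}

#' Number of extractor forward passes performed so far
#' @param object a fitted model holding a forward counter.
#' @return integer count (see also [reset_forward_count()]).
#' @export
forward_count <- function(object) object$net$n_forward$count

#' @rdname forward_count
#' @export
reset_forward_count <- function(object) {
  object$net$n_forward$count <- 0L
  invisible(object)
}

#' @export
print.sngp <- function(x, ...) {
  cat(sprintf("SNGP classifier: %d-d input, hidden [%s], RFF dim %d, tau %.3g, c %.3g\n",
              x$net$d_in, paste(x$net$hidden, collapse = ", "),
              x$net$head$D, x$net$head$tau, x$config$c))
  cat(sprintf("  trained on %d tiles; best validation accuracy %.3f\n",
              x$n_train, x$val_accuracy))
  invisible(x)
}

#' @export
summary.sngp <- function(object, ...) {
  print(object)
  lam <- vapply(object$net$W, function(w) svd(w, nu = 0, nv = 0)$d[1], numeric(1))
  cat("  hidden-layer spectral norms:", paste(sprintf("%.3f", lam), collapse = ", "), "\n")
  cat(sprintf("  validation-accuracy trace: %s\n",
              paste(sprintf("%.2f", object$history$val_accuracy), collapse = " ")))
  invisible(object)
}

#' @export
coef.sngp <- function(object, ...) object$net$head$beta

#' Fit a dropout MLP baseline classifier
#'
#' Conventional dense-output MLP with dropout in the hidden layers, used as
#' the Monte Carlo dropout uncertainty baseline: at inference the dropout
#' masks stay active and predictions are averaged over repeated passes.
#'
#' @inheritParams sngp
#' @return an object of class `dropout_net`.
#' @export
dropout_net <- function(x, y = NULL,
                        config = sngp_config(dropout = c(0.1, 0.1),
                                             spectral_norm = FALSE),
                        validation = NULL) {
  xy <- resolve_xy(x, y)
  if (is.null(validation)) {
    val_idx <- split_validation(xy, config$val_fraction, config$seed)
    Xtr <- xy$X[!val_idx, , drop = FALSE]; ytr <- xy$y[!val_idx]
    Xval <- xy$X[val_idx, , drop = FALSE]; yval <- xy$y[val_idx]
  } else {
    Xtr <- xy$X; ytr <- xy$y
    vxy <- resolve_xy(validation$x, validation$y)
    Xval <- vxy$X; yval <- vxy$y
  }
  fit <- train_mlp(Xtr, ytr, Xval, yval, config, "dense")
  structure(list(net = fit$net, config = config, n_train = nrow(Xtr),
                 history = fit$history, val_accuracy = fit$val_accuracy),
            class = "dropout_net")
}

#' @export
print.dropout_net <- function(x, ...) {
  cat(sprintf("Dropout MLP baseline: hidden [%s], dropout [%s]; val accuracy %.3f\n",
              paste(x$net$hidden, collapse = ", "),
              paste(x$config$dropout, collapse = ", "), x$val_accuracy))
  invisible(x)
}

#' Monte Carlo dropout prediction
#'
#' Forward-passes each tile through the dropout-enabled network `n_passes`
#' times; class probabilities are the mean over passes and the per-tile
#' uncertainty is the standard deviation of the predicted probabilities
#' across passes (averaged over classes).
#'
#' @param model a fitted `dropout_net` (dropout rates may be 0, in which
#'   case all passes coincide and uncertainty is 0).
#' @param newdata `tile_table` or feature matrix.
#' @param n_passes number of stochastic passes (default 5; must be >= 2 for
#'   the standard deviation to be defined).
#' @param seed seed for the dropout masks.
#' @return a `predictive_output` with `probs` and `uncertainty`.
#' @export
mc_dropout_predict <- function(model, newdata, n_passes = 5L, seed = 1L) {
  if (n_passes < 2L) stop("n_passes must be >= 2: a standard deviation across passes is undefined otherwise", call. = FALSE)
  X <- if (inherits(newdata, "tile_table")) newdata$embeddings else as.matrix(newdata)
  with_stream(seed, "mc-dropout", {
    passes <- lapply(seq_len(n_passes), function(i) {
      fw <- mlp_forward(model$net, X, dropout = TRUE,
                        dropout_rates = model$config$dropout)
      softmax_rows(fw$logits)
    })
    probs <- Reduce(`+`, passes) / n_passes
    K <- ncol(probs)
    sds <- vapply(seq_len(K), function(k) {
      pk <- vapply(passes, function(p) p[, k], numeric(nrow(X)))
      apply(matrix(pk, nrow(X)), 1L, stats::sd)
    }, numeric(nrow(X)))
    u <- rowMeans(matrix(sds, nrow(X)))
    structure(list(mu = log(pmax(probs, 1e-12)), sigma2 = matrix(u^2, nrow(X), K),
                   probs = probs, uncertainty = u),
              class = "predictive_output")
  })
}
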