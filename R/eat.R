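# Ambiguity scoring and elimination of ambiguous tiles (EAT).
#
# A tile is ambiguous when the classifier cannot tell the two classes apart
# on it: s(x) = 1 - |p0 - p1|. Elimination runs in three modes: latent-space
# clustering (flag clusters without clear label dominance and drop their
# tiles), score thresholding (keep the lowest-ambiguity fraction), and
# random elimination (the rate-matched baseline).

#' Ambiguity score of binary class probabilities
#'
#' @param probs n x 2 matrix (or length-2 vector) of class probabilities.
#' @return scores `1 - |p0 - p1|` in `[0, 1]`; 0 = fully discernible,
#'   1 = uninformative.
#' @export
ambiguity_score <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)
  probs <- check_prob_matrix(probs)
  if (ncol(probs) != 2L)
    stop("ambiguity score is defined for binary classification only", call. = FALSE)
  1 - abs(probs[, 1L] - probs[, 2L])
}

#' Select the number of latent clusters by silhouette
#'
#' Runs k-means for each candidate k and returns the k maximizing the mean
#' silhouette width. For n > `subsample` tiles a seeded subsample is used.
#'
#' @param embeddings n x d matrix of (latent) tile representations.
#' @param k_range candidate cluster counts (at least 2 values).
#' @param seed integer seed.
#' @param subsample silhouette subsample cap (default 20000).
#' @return the selected k, with the per-k silhouette profile as attribute
#'   `silhouette`.
#' @export
select_k <- function(embeddings, k_range = 2:6, seed = 1L, subsample = 20000L) {
  embeddings <- as.matrix(embeddings)
  if (length(k_range) < 2L) stop("k_range must contain at least 2 candidates", call. = FALSE)
  if (nrow(embeddings) <= max(k_range)) stop("need more points than max(k_range)", call. = FALSE)
  if (all(apply(embeddings, 2L, stats::var) == 0))
    stop("degenerate data: all points identical", call. = FALSE)
  with_stream(seed, "select-k", {
    idx <- if (nrow(embeddings) > subsample) sample(nrow(embeddings), subsample)
           else seq_len(nrow(embeddings))
    X <- embeddings[idx, , drop = FALSE]
    d <- stats::dist(X)
    sil <- vapply(k_range, function(k) {
      km <- stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L)
      mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    }, numeric(1))
    structure(k_range[which.max(sil)],
              silhouette = stats::setNames(sil, k_range))
  })
}

#' Cluster latent tile representations
#'
#' @param embeddings n x d matrix.
#' @param k number of clusters (>= 2, <= n).
#' @param seed integer seed (assignments reproducible).
#' @param centers optional initial centers (k x d).
#' @return list with `centers`, `assignments` (1..k) and `inertia`.
#' @export
fit_clusters <- function(embeddings, k, seed = 1L, centers = NULL) {
  embeddings <- as.matrix(embeddings)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(embeddings)) stop("k exceeds the number of points", call. = FALSE)
  with_stream(seed, "kmeans", {
    km <- if (is.null(centers))
      stats::kmeans(embeddings, centers = k, nstart = 20L, iter.max = 100L)
    else stats::kmeans(embeddings, centers = centers, iter.max = 100L)
    list(centers = km$centers, assignments = km$cluster, inertia = km$tot.withinss)
  })
}

#' Flag clusters lacking label dominance
#'
#' A cluster is ambiguous when no weak label reaches the dominance
#' threshold among its tiles. Mean ambiguity per cluster is reported when
#' scores are supplied (expected higher in flagged clusters).
#'
#' @param assignments per-tile cluster index (1..k).
#' @param labels per-tile weak labels.
#' @param dominance_threshold fraction above which a label dominates
#'   (default 0.7).
#' @param ambiguity optional per-tile ambiguity scores.
#' @return list with `ambiguous_ids`, `label_fraction` (max label share per
#'   cluster) and `mean_ambiguity` per cluster (NA without scores).
#' @export
identify_ambiguous <- function(assignments, labels, dominance_threshold = 0.7,
                               ambiguity = NULL) {
  ks <- sort(unique(assignments))
  frac <- vapply(ks, function(k) {
    tab <- table(labels[assignments == k])
    max(tab) / sum(tab)
  }, numeric(1))
  amb <- if (is.null(ambiguity)) rep(NA_real_, length(ks))
         else vapply(ks, function(k) mean(ambiguity[assignments == k]), numeric(1))
  list(ambiguous_ids = ks[frac < dominance_threshold],
       label_fraction = stats::setNames(frac, ks),
       mean_ambiguity = stats::setNames(amb, ks))
}

#' Fit an ambiguity index
#'
#' The index defines which tiles are eliminated. In `cluster` mode, k-means
#' is fitted to latent tile representations and clusters without clear weak
#' label dominance are flagged; new tiles are assigned to the nearest center.
#' In `threshold` mode, the ambiguity-score value at the `retain_rate`
#' quantile of the fitting scores becomes a fixed cutoff (so elimination is
#' idempotent). In `random` mode, a seeded per-tile draw keeps each tile
#' with probability `retain_rate` — the rate-matched random-elimination
#' baseline.
#'
#' @param mode one of "cluster", "threshold", "random".
#' @param embeddings latent representations (cluster mode).
#' @param labels per-tile weak labels (cluster mode).
#' @param scores per-tile ambiguity scores (threshold mode fitting set).
#' @param k cluster count; `NULL` selects it by silhouette.
#' @param dominance_threshold label-dominance cutoff (cluster mode).
#' @param retain_rate fraction of tiles kept (threshold/random modes).
#' @param per_slide logical; when TRUE, threshold/random modes keep
#'   `ceiling(retain_rate * n)` tiles per slide (every slide keeps at least
#'   one tile) instead of applying a cohort-wide cutoff. Per-slide retention
#'   is rank-based and therefore not idempotent.
#' @param seed integer seed.
#' @return an object of class `ambiguity_index`.
#' @export
ambiguity_index <- function(mode = c("cluster", "threshold", "random"),
                            embeddings = NULL, labels = NULL, scores = NULL,
                            k = NULL, dominance_threshold = 0.7,
                            retain_rate = 1, per_slide = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (retain_rate <= 0 || retain_rate > 1)
    stop("retain_rate must lie in (0, 1]", call. = FALSE)
  out <- list(mode = mode, retain_rate = retain_rate, per_slide = per_slide,
              seed = seed, dominance_threshold = dominance_threshold)
  if (mode == "cluster") {
    stopifnot(!is.null(embeddings), !is.null(labels))
    if (is.null(k)) k <- as.integer(select_k(embeddings, seed = seed))
    cl <- fit_clusters(embeddings, k, seed = seed)
    flag <- identify_ambiguous(cl$assignments, labels, dominance_threshold,
                               ambiguity = scores)
    out$k <- k
    out$centers <- cl$centers
    out$assignments <- cl$assignments
    out$ambiguous_ids <- flag$ambiguous_ids
    out$label_fraction <- flag$label_fraction
    out$mean_ambiguity <- flag$mean_ambiguity
  } else if (mode == "threshold" && !per_slide) {
    if (is.null(scores)) stop("threshold mode requires fitting scores", call. = FALSE)
    out$score_threshold <- if (retain_rate >= 1) Inf
                           else stats::quantile(scores, retain_rate, names = FALSE)
  }
  structure(out, class = "ambiguity_index")
}

#' @export
print.ambiguity_index <- function(x, ...) {
  cat(sprintf("Ambiguity index [%s mode]", x$mode))
  if (x$mode == "cluster")
    cat(sprintf(": k = %d, ambiguous cluster(s) {%s}",
                x$k, paste(x$ambiguous_ids, collapse = ", ")))
  else cat(sprintf(": retain_rate = %.3g", x$retain_rate))
  cat("\n")
  invisible(x)
}

nearest_center <- function(embeddings, centers) {
  d2 <- outer(rowSums(embeddings^2), rep(1, nrow(centers))) -
    2 * tcrossprod(embeddings, centers) +
    outer(rep(1, nrow(embeddings)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

# FNV-style string hash with extra multiplicative mixing rounds so that
# near-identical ids (consecutive tiles of one slide) decorrelate fully.
tile_hash_uniform <- function(ids, seed) {
  M <- 2147483647
  s <- as.integer(abs(seed) %% M)
  vapply(ids, function(id) {
    h <- 216613626
    for (ch in utf8ToInt(id)) {
      h <- bitwXor(as.integer(h), ch)
      h <- (h * 48271) %% M   # multipliers < 2^17 keep products exact in doubles
    }
    h <- bitwXor(as.integer(h), s)
    h <- (h * 48271) %% M
    h <- bitwXor(as.integer(h), as.integer(h %/% 8192))
    h <- (h * 69621) %% M
    h <- bitwXor(as.integer(h), as.integer(h %/% 131072))
    h <- (h * 16807) %% M
    h / M
  }, numeric(1), USE.NAMES = FALSE)
}

#' Eliminate ambiguous tiles
#'
#' Applies a fitted [ambiguity_index()] to a tile table. Cluster mode drops
#' tiles whose latent representation falls in an ambiguous cluster
#' (assignment by nearest Euclidean center); threshold mode keeps tiles at
#' or below the fitted score cutoff; random mode keeps a seeded
#' `retain_rate` Bernoulli sample. Slides losing all tiles are flagged and
#' must be excluded from aggregation.
#'
#' @param tiles a `tile_table`.
#' @param index a fitted `ambiguity_index`.
#' @param latents latent representations aligned with `tiles` (cluster
#'   mode; defaults to the raw embeddings).
#' @param scores per-tile ambiguity scores aligned with `tiles` (threshold
#'   mode).
#' @return list with `tiles` (filtered `tile_table`), `report` (data.frame
#'   tile_id, score, cluster, kept), `removed_fraction` and
#'   `empty_slides` (ids of slides left with no informative tiles).
#' @export
eliminate <- function(tiles, index, latents = NULL, scores = NULL) {
  stopifnot(inherits(tiles, "tile_table"), inherits(index, "ambiguity_index"))
  n <- n_tiles(tiles)
  cluster_id <- rep(NA_integer_, n)
  score <- rep(NA_real_, n)
  keep_per_slide <- function(value) {
    # keep ceiling(rate * n) lowest-value tiles within each slide
    kept <- logical(n)
    for (s in unique(tiles$manifest$slide_id)) {
      idx <- which(tiles$manifest$slide_id == s)
      n_keep <- ceiling(index$retain_rate * length(idx))
      kept[idx[order(value[idx])[seq_len(n_keep)]]] <- TRUE
    }
    kept
  }
  if (index$mode == "cluster") {
    lat <- latents %||% tiles$embeddings
    cluster_id <- nearest_center(as.matrix(lat), index$centers)
    kept <- !(cluster_id %in% index$ambiguous_ids)
  } else if (index$mode == "threshold") {
    stopifnot(!is.null(scores), length(scores) == n)
    score <- scores
    kept <- if (isTRUE(index$per_slide)) keep_per_slide(score)
            else score <= index$score_threshold
  } else {
    u <- tile_hash_uniform(tiles$manifest$tile_id, index$seed)
    kept <- if (isTRUE(index$per_slide)) keep_per_slide(u)
            else u <= index$retain_rate
  }
  report <- data.frame(tile_id = tiles$manifest$tile_id, score = score,
                       cluster = cluster_id, kept = kept,
                       stringsAsFactors = FALSE)
  before <- unique(tiles$manifest$slide_id)
  out <- tile_subset(tiles, kept)
  empty <- setdiff(before, unique(out$manifest$slide_id))
  if (length(empty) > 0L)
    warning(length(empty), " slide(s) left with no informative tiles; ",
            "excluded from aggregation")
  list(tiles = out, report = report,
       removed_fraction = 1 - mean(kept), empty_slides = empty)
}

#' Proxy tile classifier for the foundation-model path
#'
#' Ridge-free logistic regression on raw tile embeddings, standing in for
#' an AutoML tabular ensemble: all EAT needs from it is per-tile binary
#' class probabilities from which ambiguity scores are computed.
#'
#' @param train_tiles `tile_table` used to fit the proxy.
#' @param new_tiles `tile_table` (or feature matrix) to score.
#' @return n x 2 matrix of class probabilities for `new_tiles`.
#' @export
proxy_tile_probs <- function(train_tiles, new_tiles = train_tiles) {
  X <- train_tiles$embeddings
  y <- train_tiles$manifest$label
  df <- as.data.frame(X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(df, y = y),
                                     family = stats::binomial()))
  Xn <- if (inherits(new_tiles, "tile_table")) new_tiles$embeddings else as.matrix(new_tiles)
  p1 <- stats::predict(fit, newdata = as.data.frame(Xn), type = "response")
  cbind(1 - p1, p1)
}
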