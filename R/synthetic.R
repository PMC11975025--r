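# Synthetic tile/slide/patient cohort generator.
#
# Emulates the statistical structure that tile-based weakly supervised WSI
# classification assumes: two class-dominant embedding clusters, one
# high-ambiguity cluster whose tiles occur in slides of both classes, a
# patient -> slide -> tile hierarchy with weak slide-level labels propagated
# to tiles, per-patient demographic subgroups, and displaced OOD cohorts.

#' Configuration of a synthetic cohort
#'
#' Defines the geometry and sampling scheme of a synthetic tile cohort. In-D
#' tiles are drawn from three isotropic Gaussian clusters in embedding space:
#' one dominated by class-0 slides, one by class-1 slides, and one ambiguous
#' cluster whose tiles appear in slides of either class with equal frequency
#' (so its tiles carry a 50/50 weak-label mix, exactly the label noise weak
#' supervision produces). Every tile inherits the weak label of its slide.
#'
#' @param n_patients_per_class patients per class (exact, not expected).
#' @param slides_per_patient integer range `c(min, max)`; slides per patient
#'   are uniform on that range. `c(1, 1)` mimics one-slide-per-patient
#'   cohorts; `c(2, 4)` mimics multi-slide cohorts averaging ~3 slides.
#' @param tiles_per_slide integer range `c(min, max)`.
#' @param embed_dim embedding dimension (>= 2).
#' @param cluster_means 3 x embed_dim matrix of cluster centroids, rows =
#'   (class-0 dominant, class-1 dominant, ambiguous). Default places the two
#'   class centroids 4 scale units apart and the ambiguous centroid off-axis.
#' @param cluster_scales positive per-cluster isotropic standard deviations.
#' @param ambiguous_fraction fraction in `[0, 1]` of each slide's tiles drawn
#'   from the ambiguous cluster.
#' @param ood_mean_shift nonnegative distance (in scale units) of OOD cluster
#'   centroids from every In-D centroid.
#' @param subgroup_probs named list with `sex` and `race` probability vectors
#'   used to assign demographic labels per patient.
#' @param seed integer seed; identical `(config, seed)` reproduce identical
#'   cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_per_class = 50L,
                          slides_per_patient = c(1L, 1L),
                          tiles_per_slide = c(20L, 40L),
                          embed_dim = 8L,
                          cluster_means = NULL,
                          cluster_scales = c(1, 1, 1),
                          ambiguous_fraction = 2 / 3,
                          ood_mean_shift = 8,
                          subgroup_probs = list(
                            sex = c(male = 0.6, female = 0.4),
                            race = c(white = 0.72, others = 0.10, not_reported = 0.18)
                          ),
                          seed = 1L) {
  if (embed_dim < 2) stop("embed_dim must be >= 2", call. = FALSE)
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1)
    stop("ambiguous_fraction must lie in [0, 1]", call. = FALSE)
  if (any(cluster_scales < 0) || length(cluster_scales) != 3L)
    stop("cluster_scales must be 3 nonnegative values", call. = FALSE)
  if (length(slides_per_patient) != 2L || slides_per_patient[1] > slides_per_patient[2] ||
      slides_per_patient[1] < 1)
    stop("slides_per_patient must be an increasing positive range c(min, max)", call. = FALSE)
  if (length(tiles_per_slide) != 2L || tiles_per_slide[1] > tiles_per_slide[2] ||
      tiles_per_slide[1] < 1)
    stop("tiles_per_slide must be an increasing positive range c(min, max)", call. = FALSE)
  if (ood_mean_shift < 0) stop("ood_mean_shift must be nonnegative", call. = FALSE)
  if (is.null(cluster_means)) {
    cluster_means <- matrix(0, 3L, embed_dim)
    cluster_means[1, 1] <- -2
    cluster_means[2, 1] <- 2
    cluster_means[3, 2] <- 2.5
  }
  cluster_means <- as.matrix(cluster_means)
  if (!all(dim(cluster_means) == c(3L, embed_dim)))
    stop("cluster_means must be a 3 x embed_dim matrix", call. = FALSE)
  for (nm in c("sex", "race")) {
    p <- subgroup_probs[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("subgroup_probs$", nm, " must be a named probability vector", call. = FALSE)
  }
  structure(list(
    n_patients_per_class = as.integer(n_patients_per_class),
    slides_per_patient = as.integer(slides_per_patient),
    tiles_per_slide = as.integer(tiles_per_slide),
    embed_dim = as.integer(embed_dim),
    cluster_means = cluster_means,
    cluster_scales = as.numeric(cluster_scales),
    ambiguous_fraction = ambiguous_fraction,
    ood_mean_shift = ood_mean_shift,
    subgroup_probs = subgroup_probs,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  patients/class: %d   slides/patient: %d..%d   tiles/slide: %d..%d\n",
              x$n_patients_per_class, x$slides_per_patient[1], x$slides_per_patient[2],
              x$tiles_per_slide[1], x$tiles_per_slide[2]))
  cat(sprintf("  embed_dim: %d   ambiguous_fraction: %.3f   ood_mean_shift: %.1f   seed: %d\n",
              x$embed_dim, x$ambiguous_fraction, x$ood_mean_shift, x$seed))
  invisible(x)
}

new_tile_table <- function(embeddings, manifest) {
  stopifnot(nrow(embeddings) == nrow(manifest))
  rownames(embeddings) <- manifest$tile_id
  structure(list(embeddings = embeddings, manifest = manifest), class = "tile_table")
}

#' Number of tiles in a tile table
#' @param tiles a `tile_table`.
#' @return integer tile count.
#' @export
n_tiles <- function(tiles) nrow(tiles$manifest)

#' @export
print.tile_table <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Tile table: %d tiles, %d slides, %d patients, dim %d%s\n",
              nrow(m), length(unique(m$slide_id)), length(unique(m$patient_id)),
              ncol(x$embeddings), if (any(m$is_ood)) " [OOD]" else ""))
  invisible(x)
}

#' Subset a tile table by row index
#' @param tiles a `tile_table`.
#' @param idx logical or integer row index into the tile dimension.
#' @return a `tile_table` with the selected tiles.
#' @export
tile_subset <- function(tiles, idx) {
  new_tile_table(tiles$embeddings[idx, , drop = FALSE],
                 tiles$manifest[idx, , drop = FALSE])
}

#' Bind two tile tables (e.g. In-D and OOD) into one
#' @param ... `tile_table` objects with identical embedding dimension.
#' @return a single `tile_table`.
#' @export
tile_rbind <- function(...) {
  tabs <- list(...)
  new_tile_table(do.call(rbind, lapply(tabs, `[[`, "embeddings")),
                 do.call(rbind, lapply(tabs, `[[`, "manifest")))
}

sample_subgroups <- function(n, subgroup_probs) {
  data.frame(
    sex = sample(names(subgroup_probs$sex), n, TRUE, subgroup_probs$sex),
    race = sample(names(subgroup_probs$race), n, TRUE, subgroup_probs$race),
    stringsAsFactors = FALSE
  )
}

sample_hierarchy <- function(config, n_patients, labels, prefix) {
  sp <- config$slides_per_patient
  ts <- config$tiles_per_slide
  slides_per <- sample(seq(sp[1], sp[2]), n_patients, replace = TRUE)
  sub <- sample_subgroups(n_patients, config$subgroup_probs)
  rows <- vector("list", n_patients)
  slide_counter <- 0L
  for (i in seq_len(n_patients)) {
    pid <- sprintf("%s-P%04d", prefix, i)
    srows <- vector("list", slides_per[i])
    for (s in seq_len(slides_per[i])) {
      slide_counter <- slide_counter + 1L
      sid <- sprintf("%s-S%05d", prefix, slide_counter)
      nt <- sample(seq(ts[1], ts[2]), 1L)
      srows[[s]] <- data.frame(
        slide_id = sid, patient_id = pid, label = labels[i],
        sex = sub$sex[i], race = sub$race[i], n_tiles = nt,
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- do.call(rbind, srows)
  }
  do.call(rbind, rows)
}

draw_tiles <- function(slide_df, config, cluster_of_tile) {
  n <- length(cluster_of_tile)
  d <- config$embed_dim
  e <- matrix(stats::rnorm(n * d), n, d)
  e <- e * config$cluster_scales[cluster_of_tile] +
    config$cluster_means[cluster_of_tile, , drop = FALSE]
  e
}

#' Generate a synthetic in-distribution cohort
#'
#' Draws a patient/slide/tile hierarchy from [cohort_config()]. Tiles of a
#' class-y slide come from the class-y-dominant cluster with probability
#' `1 - ambiguous_fraction` and from the ambiguous cluster otherwise; all
#' tiles of a slide share the slide's weak label. `source_cluster` records
#' the latent generating cluster (ground truth for tests) and is not an
#' observable feature.
#'
#' @param config a [cohort_config()].
#' @return a `tile_table`: embeddings matrix plus a manifest with columns
#'   tile_id, slide_id, patient_id, label, source_cluster, is_ood, sex, race.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_stream(config$seed, "cohort-ind", {
    npc <- config$n_patients_per_class
    labels <- rep(c(0L, 1L), each = npc)
    slides <- sample_hierarchy(config, 2L * npc, labels, "IND")
    total <- sum(slides$n_tiles)
    cluster <- integer(total)
    pos <- 0L
    for (j in seq_len(nrow(slides))) {
      nt <- slides$n_tiles[j]
      amb <- stats::runif(nt) < config$ambiguous_fraction
      cl <- ifelse(amb, 3L, slides$label[j] + 1L)
      cluster[pos + seq_len(nt)] <- cl
      pos <- pos + nt
    }
    manifest <- data.frame(
      tile_id = sprintf("IND-T%07d", seq_len(total)),
      slide_id = rep(slides$slide_id, slides$n_tiles),
      patient_id = rep(slides$patient_id, slides$n_tiles),
      label = rep(slides$label, slides$n_tiles),
      source_cluster = cluster,
      is_ood = FALSE,
      sex = rep(slides$sex, slides$n_tiles),
      race = rep(slides$race, slides$n_tiles),
      stringsAsFactors = FALSE
    )
    new_tile_table(draw_tiles(slides, config, cluster), manifest)
  })
}

ood_centers <- function(config) {
  d <- config$embed_dim
  shift <- config$ood_mean_shift * mean(config$cluster_scales)
  ctr <- matrix(0, 2L, d)
  ctr[1, 2] <- -shift            # opposite side from the ambiguous centroid
  ctr[2, min(3L, d)] <- shift    # off every In-D axis
  ctr
}

#' Generate a displaced out-of-distribution cohort
#'
#' OOD tiles come from two isotropic clusters displaced by at least
#' `ood_mean_shift` scale units from every In-D centroid. Labels are
#' arbitrary (OOD units have no In-D class meaning); `is_ood` is set.
#'
#' @param config a [cohort_config()]; `ood_mean_shift` should be > 0.
#' @param n_patients number of OOD patients (0 gives an empty table).
#' @return a `tile_table` of OOD tiles.
#' @export
generate_ood_cohort <- function(config, n_patients = config$n_patients_per_class) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$ood_mean_shift == 0)
    warning("ood_mean_shift is 0: OOD tiles are indistinguishable from In-D by construction")
  with_stream(config$seed, "cohort-ood", {
    d <- config$embed_dim
    if (n_patients == 0L) {
      return(new_tile_table(
        matrix(numeric(0), 0L, d),
        data.frame(tile_id = character(0), slide_id = character(0),
                   patient_id = character(0), label = integer(0),
                   source_cluster = integer(0), is_ood = logical(0),
                   sex = character(0), race = character(0),
                   stringsAsFactors = FALSE)))
    }
    labels <- sample(c(0L, 1L), n_patients, replace = TRUE)
    slides <- sample_hierarchy(config, n_patients, labels, "OOD")
    total <- sum(slides$n_tiles)
    ctr <- ood_centers(config)
    cluster <- sample(seq_len(nrow(ctr)), total, replace = TRUE)
    scale <- mean(config$cluster_scales)
    e <- matrix(stats::rnorm(total * d), total, d) * scale +
      ctr[cluster, , drop = FALSE]
    manifest <- data.frame(
      tile_id = sprintf("OOD-T%07d", seq_len(total)),
      slide_id = rep(slides$slide_id, slides$n_tiles),
      patient_id = rep(slides$patient_id, slides$n_tiles),
      label = rep(slides$label, slides$n_tiles),
      source_cluster = 3L + cluster,
      is_ood = TRUE,
      sex = rep(slides$sex, slides$n_tiles),
      race = rep(slides$race, slides$n_tiles),
      stringsAsFactors = FALSE
    )
    new_tile_table(e, manifest)
  })
}

#' Ground-truth tile relevance mask
#'
#' Flags tiles from the class-dominant clusters as "informative" — the
#' synthetic stand-in for expert-annotated diagnostically relevant regions,
#' used to score attention efficiency.
#'
#' @param tiles a `tile_table` with `source_cluster` ground truth.
#' @return integer vector, 1 for tiles from a class-dominant cluster.
#' @export
relevance_mask <- function(tiles) {
  stopifnot(inherits(tiles, "tile_table"))
  as.integer(tiles$manifest$source_cluster %in% c(1L, 2L))
}
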