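# Readers/writers: TSV manifests + embeddings, YAML configs, JSON summaries.
# All round-trips are lossless at the precision written.

manifest_columns <- c("tile_id", "slide_id", "patient_id", "label",
                      "source_cluster", "is_ood", "sex", "race")

#' Write a cohort to disk (TSV manifest + TSV embeddings)
#'
#' @param tiles a `tile_table`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(tiles, dir) {
  stopifnot(inherits(tiles, "tile_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tiles$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  emb <- data.frame(tile_id = tiles$manifest$tile_id,
                    tiles$embeddings, check.names = FALSE)
  names(emb)[-1L] <- paste0("e", seq_len(ncol(tiles$embeddings)))
  utils::write.table(emb, file.path(dir, "embeddings.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding manifest.tsv and embeddings.tsv.
#' @return a `tile_table`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  ef <- file.path(dir, "embeddings.tsv")
  for (f in c(mf, ef)) if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing) > 0L)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  emb <- utils::read.delim(ef, stringsAsFactors = FALSE)
  if (names(emb)[1L] != "tile_id") stop("embeddings.tsv must start with tile_id",
                                        call. = FALSE)
  bad <- which(emb$tile_id != manifest$tile_id)
  if (length(bad) > 0L)
    stop("embeddings row ", bad[1L] + 1L, " does not match the manifest",
         call. = FALSE)
  new_tile_table(as.matrix(emb[, -1L, drop = FALSE]), manifest)
}

#' Write / read a cohort configuration as YAML
#' @param config a [cohort_config()].
#' @param path YAML file path.
#' @return `read_cohort_config` returns a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$cluster_means <- apply(x$cluster_means, 1L, identity, simplify = FALSE)
  # named vectors must become YAML maps or the names are dropped
  x$subgroup_probs <- lapply(x$subgroup_probs, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$cluster_means <- do.call(rbind, x$cluster_means)
  x$subgroup_probs <- lapply(x$subgroup_probs, unlist)
  do.call(cohort_config, x)
}

#' Write per-unit prediction-set results as TSV
#'
#' @param sets a `prediction_sets` object.
#' @param unit_ids unit identifiers aligned with the sets.
#' @param level "tile", "slide" or "patient".
#' @param path output TSV path.
#' @export
write_sets_tsv <- function(sets, unit_ids, level, path) {
  lab <- apply(sets$set, 1L, function(r) paste(which(r) - 1L, collapse = ","))
  utils::write.table(
    data.frame(unit_id = unit_ids, level = level, set = lab,
               size = sets$set_size, category = sets$category),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a summary list as JSON
#' @param x a list of summary quantities.
#' @param path output JSON path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

# Content hash for run manifests (FNV-style; multipliers < 2^17 keep the
# modular products exact in doubles).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  M <- 2147483647
  h <- 216613626
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), ch)
    h <- (h * 48271) %% M
  }
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest recording config hash, seed and package version
#' @param dir output directory.
#' @param config the configuration object used.
#' @param seed the run seed.
#' @export
write_run_manifest <- function(dir, config, seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_json(list(
    config_hash = config_hash(unclass(config)),
    seed = seed,
    package = as.character(utils::packageVersion("wsitrust")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), file.path(dir, "run_manifest.json"))
}
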