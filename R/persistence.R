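# On-disk artifact formats: feature-tensor stores, per-block PCA archives,
# risk-model archives, and importance/enrichment reports. Arrays are
# serialized per sample; metadata travels as JSON or TSV next to them.

#' Write a feature store to a directory
#'
#' One serialized array per sample plus a JSON manifest (samples, windows,
#' shape, extractor name) and a track-label TSV.
#'
#' @param features A `feature_store`.
#' @param dir Output directory (created if absent).
#' @export
write_feature_store <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(features$samples))
    saveRDS(features$values[s, , , , , drop = FALSE],
            file.path(dir, paste0(features$samples[s], ".rds")))
  jsonlite::write_json(
    list(samples = features$samples, extractor = features$extractor,
         shape = dim(features$values), windows = features$windows),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  write.table(data.frame(track = features$labels),
              file.path(dir, "tracks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a feature store written by [write_feature_store()]
#'
#' @param dir The store directory.
#' @return A `feature_store`.
#' @export
read_feature_store <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- read.delim(file.path(dir, "tracks.tsv"))$track
  samples <- manifest$samples
  shape <- as.integer(manifest$shape)
  values <- array(NA_real_, dim = shape,
                  dimnames = list(samples, c("hap1", "hap2"), NULL, NULL, labels))
  for (s in seq_along(samples))
    values[s, , , , ] <- readRDS(file.path(dir, paste0(samples[s], ".rds")))
  structure(
    list(values = values, samples = samples,
         windows = as.data.frame(manifest$windows), labels = labels,
         extractor = manifest$extractor, n_extract_calls = NA_integer_),
    class = "feature_store")
}

#' Persist per-block PCA models as a single archive
#'
#' Serialized model arrays plus a JSON sidecar with window/bin ids,
#' `d_prime` and the fit-population hash.
#'
#' @param pca A `block_pca`.
#' @param path Archive path (an `.rds` file; metadata written to
#'   `<path>.json`).
#' @export
save_block_pca <- function(pca, path) {
  saveRDS(pca, path)
  k <- length(pca$models[[1]])
  jsonlite::write_json(
    list(d_prime = pca$d_prime, n_train = pca$n_train,
         fit_hash = pca$fit_hash, n_windows = length(pca$models),
         bins_per_window = k),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_block_pca
#' @export
load_block_pca <- function(path) readRDS(path)

#' Persist a fitted risk model with its provenance
#'
#' @param model A `risk_model`.
#' @param path Archive path (`.rds`; provenance JSON at `<path>.json`).
#' @export
save_risk_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    c(list(kind = model$kind, n_features = model$n_features,
           seed = model$seed), model$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) readRDS(path)

#' Write reduced block features as TSV (sample x feature)
#'
#' @param reduced A `block_features` from [reduce_cohort()].
#' @param path Output path.
#' @export
write_reduced_tsv <- function(reduced, path) {
  out <- data.frame(sample = rownames(reduced$x), reduced$x,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write importance scores and enrichment fractions as TSV reports
#'
#' @param track_scores Named numeric vector from [track_importance()].
#' @param bin_scores Data.frame from [bin_importance()], with genomic
#'   intervals attached via [window_bin_intervals()] when available.
#' @param enrichment Optional data.frame (set, track, fraction, numerator,
#'   denominator).
#' @param dir Output directory.
#' @export
write_importance_reports <- function(track_scores = NULL, bin_scores = NULL,
                                     enrichment = NULL, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(track_scores))
    write.table(data.frame(track = names(track_scores), score = track_scores),
                file.path(dir, "track_importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bin_scores))
    write.table(bin_scores, file.path(dir, "bin_importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(enrichment))
    write.table(enrichment, file.path(dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
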