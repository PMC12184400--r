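# Normalized Gini (gain) importance vector of a fitted xgboost model over
# all feature columns, zeros for features never used. Internal.
gini_importance <- function(fit, n_features, feature_names = NULL) {
  imp <- xgboost::xgb.importance(model = fit)
  out <- numeric(n_features)
  if (!is.null(imp) && nrow(imp) > 0) {
    idx <- if (!is.null(feature_names)) match(imp$Feature, feature_names)
           else as.integer(sub("^f", "", imp$Feature)) + 1L
    out[idx] <- imp$Gain
    s <- sum(out)
    if (s > 0) out <- out / s
  }
  out
}

#' Per-track feature importance from per-bin models
#'
#' Trains one GBRT per bin directly on that bin's raw feature tracks
#' (diploid mean of the two haplotype rows), extracts normalized Gini
#' importances, and averages them across bins (unweighted). Bins whose
#' features have zero variance everywhere are skipped with a warning and
#' the divisor adjusted.
#'
#' @param features A `feature_store`.
#' @param labels Binary labels aligned with `features$samples`.
#' @param train Training sample indices (default all).
#' @param hyper GBRT hyperparameters; per-bin models default to 100 trees.
#' @param seed Integer seed.
#' @return A named numeric vector of length d (track labels), averaged
#'   normalized importances.
#' @export
track_importance <- function(features, labels, train = NULL,
                             hyper = gbrt_hyperparams(n_trees = 100L),
                             seed = 1L) {
  if (is.null(train)) train <- seq_along(features$samples)
  vals <- features$values
  W <- dim(vals)[3]; k <- dim(vals)[4]; d <- dim(vals)[5]
  acc <- numeric(d); used <- 0L; skipped <- 0L
  for (w in seq_len(W)) for (i in seq_len(k)) {
    x <- (vals[train, 1, w, i, , drop = TRUE] + vals[train, 2, w, i, , drop = TRUE]) / 2
    if (is.null(dim(x))) x <- matrix(x, nrow = length(train))
    if (all(apply(x, 2, function(col) var(col) == 0))) { skipped <- skipped + 1L; next }
    m <- train_risk_model(x, labels[train], kind = "gbrt-classify",
                          hyper = hyper, seed = child_seed(seed, paste0("bin", w, ".", i)))
    acc <- acc + gini_importance(m$fit, d)
    used <- used + 1L
  }
  if (skipped > 0) warning(sprintf("%d zero-variance bin(s) skipped", skipped))
  if (used == 0L) stop_epiprs("no bin had usable features")
  setNames(acc / used, features$labels)
}

#' Bin-level importance from the main risk model
#'
#' Averages the Gini importances of each bin's principal-component
#' features in the trained model, yielding a per-bin predictive ranking.
#'
#' @param model A `risk_model` (GBRT kind) trained on reduced features.
#' @param map The feature map from [reduce_cohort()] (or
#'   [concat_blocks()]), one row per model feature with `window` and `bin`
#'   columns; must partition the feature indices.
#' @return A data.frame with one row per (window, bin): `window`, `bin`,
#'   `score`.
#' @export
bin_importance <- function(model, map) {
  if (nrow(map) != model$n_features)
    stop_epiprs("feature map (%d rows) does not partition the %d model features",
                nrow(map), model$n_features)
  imp <- gini_importance(model$fit, model$n_features, model$feature_names)
  key <- paste(map$block %||% "", map$window, map$bin, sep = ".")
  agg <- tapply(imp, key, mean)
  first <- !duplicated(key)
  out <- data.frame(window = map$window[first], bin = map$bin[first],
                    score = as.numeric(agg[key[first]]))
  if (!is.null(map$block)) out <- cbind(block = map$block[first], out)
  out[order(out$window, out$bin), , drop = FALSE]
}

#' Top and bottom quantile bin sets
#'
#' Both sets have `max(1, floor(q * M))` bins; ties are broken by bin
#' order, deterministically.
#'
#' @param scores Numeric vector of per-bin importances (length M).
#' @param q Quantile in (0, 0.5).
#' @return A list with integer index vectors `top` and `bottom`.
#' @export
quantile_bins <- function(scores, q) {
  if (q <= 0 || q >= 0.5) stop_epiprs("q must lie strictly between 0 and 0.5")
  M <- length(scores)
  k <- max(1L, floor(q * M))
  ord_desc <- order(-scores, seq_len(M))
  ord_asc <- order(scores, seq_len(M))
  list(top = sort(ord_desc[seq_len(k)]), bottom = sort(ord_asc[seq_len(k)]))
}

#' Fraction of a bin set overlapping annotation tracks
#'
#' A bin overlaps under rule `"any"` iff its genomic interval intersects at
#' least one interval of at least one track, and under rule `"all"` iff it
#' intersects every track. Optionally reports the conditional fraction of
#' the already-overlapping bins against a second track (e.g. an active-mark
#' within-open-chromatin statistic). Interval arithmetic is half-open and
#' chromosome-aware.
#'
#' @param bins Data.frame of bin intervals: `chrom`, `start`, `end`
#'   (0-based half-open); must be non-empty.
#' @param tracks A single data.frame (`chrom`, `start`, `end`) or a list of
#'   them.
#' @param rule `"any"` or `"all"`.
#' @param second Optional second annotation track for the conditional
#'   fraction.
#' @return A list with `fraction`, `n_overlap`, `n`, `hits` (logical per
#'   bin) and, when `second` is given, `conditional` (list with `fraction`,
#'   `n_overlap`, `n`).
#' @export
annotation_overlap <- function(bins, tracks, rule = c("any", "all"), second = NULL) {
  rule <- match.arg(rule)
  if (is.null(bins) || nrow(bins) == 0L) stop_epiprs("empty bin set")
  if (is.data.frame(tracks)) tracks <- list(tracks)
  gr_bins <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(start = bins$start + 1L, end = bins$end))
  hit_mat <- vapply(tracks, function(tr) {
    gr_tr <- GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(start = tr$start + 1L, end = tr$end))
    # disjoint seqlevels between bins and a track are an expected case
    # (no overlap), not a condition worth surfacing
    suppressWarnings(IRanges::overlapsAny(gr_bins, gr_tr))
  }, logical(nrow(bins)))
  if (is.null(dim(hit_mat))) hit_mat <- matrix(hit_mat, nrow = nrow(bins))
  hits <- if (rule == "any") rowSums(hit_mat) > 0 else rowSums(hit_mat) == length(tracks)
  res <- list(fraction = mean(hits), n_overlap = sum(hits), n = nrow(bins), hits = hits)
  if (!is.null(second) && any(hits)) {
    sub <- bins[hits, , drop = FALSE]
    inner <- annotation_overlap(sub, second, rule = "any")
    res$conditional <- list(fraction = inner$fraction,
                            n_overlap = inner$n_overlap, n = inner$n)
  }
  res
}

#' Genomic intervals of the bins of a fitted window set
#'
#' @param windows A window data.frame (as stored in an `epiprs` fit).
#' @param cfg The [window_config()] used.
#' @return A data.frame with `window`, `bin`, `chrom`, `start`, `end`, in
#'   (window, bin) order — aligned with [bin_importance()] output.
#' @export
window_bin_intervals <- function(windows, cfg) {
  out <- lapply(seq_len(nrow(windows)), function(w) {
    bc <- bin_coordinates(windows[w, ], cfg)
    data.frame(window = w, bin = bc$bin, chrom = windows$chrom[w],
               start = bc$start, end = bc$end)
  })
  do.call(rbind, out)
}
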