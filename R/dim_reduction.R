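#' Fit a per-bin local PCA model
#'
#' Fits principal components on the pooled feature vectors of one bin: both
#' haplotypes of every training individual enter as separate observations.
#' Components are the top eigenvectors of the sample covariance; each
#' component's sign is fixed by forcing its largest-magnitude loading
#' positive so results are reproducible across linear-algebra backends.
#' When the data rank is below `d_prime` the trailing components are zero
#' columns and the model is flagged rank-deficient (projections onto them
#' are zero).
#'
#' @param x Numeric matrix (observations x d feature tracks); at least two
#'   rows.
#' @param d_prime Number of components to retain.
#' @return An object of class `bin_pca`: list with `mean` (length d),
#'   `rotation` (d x d_prime), `evf` (explained-variance fractions, length
#'   d_prime, non-increasing), `rank`, `rank_deficient`.
#' @export
fit_bin_pca <- function(x, d_prime) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_epiprs("need at least 2 vectors to fit a bin PCA (got %d)", nrow(x))
  d_prime <- as.integer(d_prime)
  if (d_prime < 1L) stop_epiprs("d_prime must be >= 1")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0)
  ev <- sv$d^2  # proportional to eigenvalues of the covariance
  tot <- sum(ev)
  tol <- max(dim(x)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  keep <- min(d_prime, rank)
  rotation <- matrix(0, ncol(x), d_prime)
  evf <- numeric(d_prime)
  if (keep > 0L) {
    rot <- sv$v[, seq_len(keep), drop = FALSE]
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(keep)) {
      i <- which.max(abs(rot[, j]))
      if (rot[i, j] < 0) rot[, j] <- -rot[, j]
    }
    rotation[, seq_len(keep)] <- rot
    evf[seq_len(keep)] <- ev[seq_len(keep)] / tot
  }
  structure(
    list(mean = mu, rotation = rotation, evf = evf, rank = rank,
         rank_deficient = rank < d_prime),
    class = "bin_pca"
  )
}

#' Project feature vectors with a fitted bin PCA
#'
#' @param model A `bin_pca`.
#' @param x Matrix (rows = observations) or a single vector of length d.
#' @return Matrix of centered projections (observations x d_prime).
#' @export
project_bin_pca <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(x, 2, model$mean) %*% model$rotation
}

#' Fit per-bin PCA models over all windows of a feature store
#'
#' One [fit_bin_pca()] per (window, bin), fitted on the pooled
#' maternal+paternal vectors of the given training samples only; held-out
#' samples are later transformed with these frozen models.
#'
#' @param features A `feature_store`.
#' @param d_prime Components per bin.
#' @param train Integer or character indices of the training samples
#'   (defaults to all samples).
#' @return An object of class `block_pca`: list of per-window lists of
#'   `bin_pca` models, plus `d_prime`, `windows`, `n_train` and a hash of
#'   the fit population.
#' @export
fit_block_pca <- function(features, d_prime, train = NULL) {
  if (is.null(train)) train <- seq_along(features$samples)
  if (is.character(train)) train <- match(train, features$samples)
  vals <- features$values
  W <- dim(vals)[3]; k <- dim(vals)[4]
  models <- vector("list", W)
  for (w in seq_len(W)) {
    models[[w]] <- vector("list", k)
    for (i in seq_len(k)) {
      x <- rbind(vals[train, 1, w, i, , drop = TRUE],
                 vals[train, 2, w, i, , drop = TRUE])
      models[[w]][[i]] <- fit_bin_pca(x, d_prime)
    }
  }
  structure(
    list(models = models, d_prime = as.integer(d_prime),
         windows = features$windows, n_train = length(train),
         fit_hash = fnv1a_hash(features$samples[train])),
    class = "block_pca"
  )
}

#' Reduce a cohort's feature tensors to per-sample block feature vectors
#'
#' Per bin, the two haplotype rows are projected with the frozen bin model
#' and combined under the diploid rule (default: mean, which is invariant
#' to haplotype order); the per-bin vectors are concatenated in
#' (window, bin, component) order.
#'
#' @param features A `feature_store`.
#' @param pca A `block_pca` fitted on the same window set.
#' @param combine Diploid combination rule: `"mean"`, `"sum"` or `"concat"`
#'   (concat doubles the output length and is not haplotype-order
#'   invariant).
#' @param samples Samples to reduce (default all).
#' @return An object of class `block_features`: list with `x` (samples x
#'   M*d_prime matrix, or twice that for concat) and `map` (data.frame
#'   `window`, `bin`, `comp`, one row per column of `x`).
#' @export
reduce_cohort <- function(features, pca, combine = c("mean", "sum", "concat"),
                          samples = NULL) {
  combine <- match.arg(combine)
  if (is.null(samples)) samples <- features$samples
  idx <- if (is.character(samples)) match(samples, features$samples) else samples
  if (anyNA(idx)) stop_epiprs("unknown samples in reduce_cohort")
  vals <- features$values
  W <- dim(vals)[3]; k <- dim(vals)[4]; dp <- pca$d_prime
  per_bin <- if (combine == "concat") 2L * dp else dp
  out <- matrix(NA_real_, length(idx), W * k * per_bin)
  map <- data.frame(
    window = rep(seq_len(W), each = k * per_bin),
    bin = rep(rep(seq_len(k), each = per_bin), times = W),
    comp = rep(seq_len(per_bin), times = W * k)
  )
  col <- 0L
  for (w in seq_len(W)) {
    mods <- pca$models[[w]]
    if (is.null(mods)) stop_epiprs("missing PCA models for window %d", w)
    for (i in seq_len(k)) {
      m <- mods[[i]]
      if (is.null(m)) stop_epiprs("missing PCA model for window %d bin %d", w, i)
      p1 <- project_bin_pca(m, vals[idx, 1, w, i, , drop = TRUE])
      p2 <- project_bin_pca(m, vals[idx, 2, w, i, , drop = TRUE])
      comb <- switch(combine,
        mean = (p1 + p2) / 2,
        sum = p1 + p2,
        concat = cbind(p1, p2))
      out[, col + seq_len(per_bin)] <- comb
      col <- col + per_bin
    }
  }
  rownames(out) <- features$samples[idx]
  colnames(out) <- paste0("w", map$window, ".b", map$bin, ".pc", map$comp)
  structure(list(x = out, map = map, d_prime = dp, combine = combine),
            class = "block_features")
}

#' Reduce a single sample
#'
#' @inheritParams reduce_cohort
#' @param sample One sample id or index.
#' @return Numeric vector of length `M * d_prime` (ordered by window, bin,
#'   component).
#' @export
reduce_sample <- function(features, pca, sample, combine = "mean") {
  reduce_cohort(features, pca, combine = combine, samples = sample)$x[1, ]
}

#' Concatenate per-block feature sets into a global feature matrix
#'
#' Blocks are ordered canonically (block id ascending) regardless of the
#' input order; every block must cover the same samples.
#'
#' @param block_sets Named list of `block_features` (names are block ids).
#' @return A list with `x` (samples x total-features matrix) and `map`
#'   (per-column data.frame with a `block` column prepended).
#' @export
concat_blocks <- function(block_sets) {
  ids <- sort(names(block_sets))
  if (is.null(ids) || any(!nzchar(ids))) stop_epiprs("block_sets must be a named list")
  ref <- rownames(block_sets[[ids[1]]]$x)
  xs <- vector("list", length(ids)); maps <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    bs <- block_sets[[ids[j]]]
    if (!identical(sort(rownames(bs$x)), sort(ref)))
      stop_epiprs("block %s does not cover the same samples", ids[j])
    xs[[j]] <- bs$x[ref, , drop = FALSE]
    maps[[j]] <- cbind(block = ids[j], bs$map)
  }
  x <- do.call(cbind, xs)
  map <- do.call(rbind, maps)
  colnames(x) <- paste0(map$block, ".", colnames(x))
  list(x = x, map = map)
}
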