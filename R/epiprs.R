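#' Fit an epigenome-aware polygenic risk model
#'
#' The central fitting function of the package. Starting from phased SNV
#' genotypes, per-contig reference sequences, binary phenotypes and LD
#' block definitions, it runs the full chain: stratified train/test split;
#' association scan on the training split (or externally supplied GWAS
#' summary statistics); p-value-threshold block selection; window tiling;
#' diploid personal-genome construction; sequence-to-feature extraction;
#' per-bin PCA fitted on the training samples only; diploid combination and
#' concatenation into block feature vectors; gradient-boosted risk model;
#' and evaluation on the held-out test set (auROC and its lambda index).
#'
#' @param data Either a `regpheno_sim` (simulated dataset) or a list with
#'   `variants` (`phased_variants`), `references` (named contig sequences),
#'   `blocks` (data.frame `id`, `chrom`, `start`, `end`) and `phenotypes`
#'   (data.frame `sample`, `label`), as returned by [read_dataset()].
#' @param extractor A `seq_extractor` (its geometry drives the tiling).
#' @param d_prime Principal components retained per bin.
#' @param P0 P-value threshold for block selection; `NULL` keeps every
#'   block (useful when blocks were preselected upstream).
#' @param summary_stats Optional external GWAS summary statistics
#'   (data.frame `chrom`, `pos`, `id`, `p`); bypasses the internal scan.
#' @param train_frac Training fraction of the stratified split.
#' @param combine Diploid combination rule (see [reduce_cohort()]).
#' @param kind Risk model kind (see [train_risk_model()]).
#' @param hyper GBRT hyperparameters.
#' @param seed Integer seed controlling the split and model training.
#' @return An object of class `epiprs` with components `split`,
#'   `selection`, `windows`, `pca`, `features_map`, `model`, `scores`
#'   (per-sample data.frame), `auroc`, `lambda`, `extractor_name`,
#'   `d_prime`.
#' @examples
#' cfg <- sim_config(n = 120, causal_per_gene = 24, m_direct = 24,
#'                   m_neutral = 12, n_tf = 4, seed = 7)
#' ex <- synthetic_extractor(cfg$geometry, d = 8, n_motifs = 4, seed = 7)
#' sim <- regpheno(cfg, extractor = ex)
#' fit <- epiprs(sim, extractor = ex, d_prime = 2, seed = 7)
#' fit
#' @export
epiprs <- function(data, extractor, d_prime = 5L, P0 = NULL,
                   summary_stats = NULL, train_frac = 0.8,
                   combine = "mean", kind = "gbrt-classify",
                   hyper = gbrt_hyperparams(), seed = 1L) {
  if (inherits(data, "regpheno_sim")) {
    inputs <- list(variants = cohort_to_variants(data$cohort),
                   references = data$cohort$references,
                   blocks = data$cohort$blocks,
                   phenotypes = data.frame(sample = data$cohort$samples,
                                           label = data$labels))
  } else inputs <- data
  variants <- inputs$variants
  labels <- inputs$phenotypes$label[match(variants$samples, inputs$phenotypes$sample)]
  if (anyNA(labels)) stop_epiprs("phenotypes missing for some samples")
  n <- length(labels)
  cfg <- extractor$cfg

  split <- split_cohort(labels, frac = train_frac, seed = seed)

  # block selection on the training split only (leakage control)
  if (is.null(summary_stats) && !is.null(P0)) {
    D <- t(variants$a1 + variants$a2)
    poly <- apply(D[split$train, , drop = FALSE], 2, function(x) length(unique(x)) > 1)
    summary_stats <- assoc_scan(D[split$train, poly, drop = FALSE],
                                labels[split$train], variants$sites[poly, ])
  }
  if (!is.null(P0)) {
    selection <- select_blocks(summary_stats, inputs$blocks, P0)
    blocks <- selection[selection$selected, , drop = FALSE]
    if (nrow(blocks) == 0L) stop_epiprs("no block passes the P0=%g threshold", P0)
  } else {
    selection <- inputs$blocks
    selection$selected <- TRUE
    blocks <- inputs$blocks
  }

  windows <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    w <- tile_block(blocks[b, ], cfg,
                    contig_length = nchar(inputs$references[[blocks$chrom[b]]]))
    w$block <- blocks$id[b]
    w
  }))

  store <- build_cohort_haplotypes(inputs$references, variants)
  feats <- extract_cohort(store, windows, extractor)
  pca <- fit_block_pca(feats, d_prime, train = split$train)
  red <- reduce_cohort(feats, pca, combine = combine)
  model <- train_risk_model(
    red$x[split$train, , drop = FALSE], labels[split$train],
    kind = kind, hyper = hyper, seed = seed,
    provenance = list(blocks = blocks$id, d_prime = d_prime,
                      extractor = extractor$name, combine = combine,
                      pca_hash = pca$fit_hash))
  test_scores <- predict(model, red$x[split$test, , drop = FALSE])
  A <- auroc(test_scores, labels[split$test])
  scores <- data.frame(
    sample = variants$samples[c(split$train, split$test)],
    split = rep(c("train", "test"), c(length(split$train), length(split$test))),
    label = labels[c(split$train, split$test)],
    score = c(predict(model, red$x[split$train, , drop = FALSE]), test_scores))
  structure(
    list(call = match.call(), split = split, selection = selection,
         windows = windows, pca = pca, features_map = red$map, model = model,
         scores = scores, auroc = A, lambda = lambda_index(A),
         extractor_name = extractor$name, d_prime = as.integer(d_prime),
         combine = combine, seed = as.integer(seed)),
    class = "epiprs"
  )
}

#' @export
print.epiprs <- function(x, ...) {
  nb <- sum(x$selection$selected)
  cat("Epigenome-aware polygenic risk model\n")
  cat(sprintf("  %d LD block(s), %d windows, %d features (%d PCs/bin, %s rule), extractor %s\n",
              nb, nrow(x$windows), x$model$n_features, x$d_prime, x$combine,
              x$extractor_name))
  cat(sprintf("  test auROC A = %.4f, lambda = (A - 0.5)/0.5 = %.4f\n",
              x$auroc, x$lambda))
  invisible(x)
}

#' @export
summary.epiprs <- function(object, ...) {
  s <- object$scores
  res <- list(
    auroc = object$auroc, lambda = object$lambda,
    n_train = sum(s$split == "train"), n_test = sum(s$split == "test"),
    case_frac_test = mean(s$label[s$split == "test"]),
    n_blocks = sum(object$selection$selected),
    n_windows = nrow(object$windows),
    n_features = object$model$n_features,
    model = object$model$kind)
  class(res) <- "summary.epiprs"
  res
}

#' @export
print.summary.epiprs <- function(x, ...) {
  cat(sprintf(paste0(
    "epiprs fit: %s on %d features (%d blocks, %d windows)\n",
    "  train n = %d, test n = %d (case fraction %.2f)\n",
    "  test auROC = %.4f, lambda = %.4f\n"),
    x$model, x$n_features, x$n_blocks, x$n_windows,
    x$n_train, x$n_test, x$case_frac_test, x$auroc, x$lambda))
  invisible(x)
}

#' Predict risk scores for new samples
#'
#' Rebuilds haplotype sequences for the new samples over the fitted
#' windows, extracts features with the same extractor, transforms them with
#' the frozen per-bin PCA models, and scores with the trained risk model.
#'
#' @param object A fitted `epiprs` object.
#' @param newdata A list with `variants` (`phased_variants` for the new
#'   samples) and `references` (the same contigs used in fitting).
#' @param extractor The `seq_extractor` used in fitting.
#' @param ... Unused.
#' @return A data.frame with `sample` and `score`.
#' @export
predict.epiprs <- function(object, newdata, extractor, ...) {
  if (!identical(extractor$name, object$extractor_name))
    warning("extractor name differs from the one used in fitting")
  store <- build_cohort_haplotypes(newdata$references, newdata$variants)
  feats <- extract_cohort(store, object$windows, extractor)
  red <- reduce_cohort(feats, object$pca, combine = object$combine)
  data.frame(sample = newdata$variants$samples,
             score = predict(object$model, red$x))
}

#' ROC curve of a fitted model
#'
#' @param x A fitted `epiprs` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epiprs <- function(x, ...) {
  s <- x$scores[x$scores$split == "test", ]
  thr <- sort(unique(c(-Inf, s$score, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(s$score[s$label == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(s$score[s$label == 0] >= t), 0)
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (test auROC = %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(data.frame(fpr = fpr, tpr = tpr))
}
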