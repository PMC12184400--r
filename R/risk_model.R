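#' Stratified train/test split
#'
#' Randomly assigns a fraction of samples to training, stratified by class
#' label (the default, matching an 80%/20% case-control-balanced split) or
#' by whole groups when a grouping vector is given (no group then spans
#' both sets).
#'
#' @param labels Binary class labels (or any vector with >= 2 members per
#'   class when stratifying).
#' @param frac Training fraction in (0, 1).
#' @param stratify Stratify by label (default TRUE).
#' @param group Optional grouping vector; whole groups are assigned to one
#'   side.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, frac = 0.8, stratify = TRUE, group = NULL, seed = 1L) {
  if (frac <= 0 || frac >= 1) stop_epiprs("train fraction must lie strictly between 0 and 1")
  n <- length(labels)
  set.seed(child_seed(seed, "split"))
  if (!is.null(group)) {
    groups <- sample(unique(group))
    train <- integer(0)
    for (g in groups) {
      idx <- which(group == g)
      if (length(train) + length(idx) <= frac * n) train <- c(train, idx)
    }
    if (length(train) == 0L) train <- which(group == groups[1])
    return(list(train = sort(train), test = sort(setdiff(seq_len(n), train))))
  }
  if (stratify) {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < 2L) stop_epiprs("class '%s' has fewer than 2 members", cl)
      k <- round(frac * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, k))
    }
  } else {
    k <- min(max(round(frac * n), 1L), n - 1L)
    train <- sample(n, k)
  }
  list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
}

#' Default gradient-boosting hyperparameters
#'
#' 500 trees of depth 3, learning rate 0.05, row subsampling 0.8, with
#' early stopping on a 10% validation carve-out of the training set.
#'
#' @param n_trees,max_depth,learning_rate,subsample,early_stopping_rounds,validation_fraction
#'   Standard GBRT knobs.
#' @return A named list of hyperparameters.
#' @export
gbrt_hyperparams <- function(n_trees = 500L, max_depth = 3L, learning_rate = 0.05,
                             subsample = 0.8, early_stopping_rounds = 20L,
                             validation_fraction = 0.1) {
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       learning_rate = learning_rate, subsample = subsample,
       early_stopping_rounds = as.integer(early_stopping_rounds),
       validation_fraction = validation_fraction)
}

#' Train a risk model
#'
#' `gbrt-classify` / `gbrt-regress` fit gradient-boosted trees (xgboost)
#' with a seeded 10% validation carve-out for early stopping;
#' `linear-penalized` fits an L2-regularized (ridge) logistic or linear
#' model by cross-validated glmnet on the same matrix — the package's
#' stand-in for summary-statistic linear PRS methods. All fits are
#' deterministic given the seed.
#'
#' @param x Numeric feature matrix (samples x features), finite.
#' @param y Labels: binary for classification, real for regression.
#' @param kind One of `"gbrt-classify"`, `"gbrt-regress"`,
#'   `"linear-penalized"`.
#' @param hyper Hyperparameters ([gbrt_hyperparams()] for the GBRT kinds).
#' @param seed Integer seed.
#' @param provenance Optional list recording feature provenance (block ids,
#'   d_prime, extractor name, ...), stored in the model.
#' @return An object of class `risk_model`.
#' @export
train_risk_model <- function(x, y,
                             kind = c("gbrt-classify", "gbrt-regress", "linear-penalized"),
                             hyper = gbrt_hyperparams(), seed = 1L,
                             provenance = list()) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop_epiprs("feature matrix has zero columns")
  if (!all(is.finite(x))) stop_epiprs("non-finite feature values")
  n <- nrow(x)
  fit <- NULL; best_iter <- NA_integer_
  if (kind %in% c("gbrt-classify", "gbrt-regress")) {
    classify <- kind == "gbrt-classify"
    if (classify && !all(y %in% c(0, 1))) stop_epiprs("classification labels must be 0/1")
    set.seed(child_seed(seed, "carveout"))
    n_val <- max(1L, round(hyper$validation_fraction * n))
    val <- if (classify) {
      v <- integer(0)
      for (cl in 0:1) {
        idx <- which(y == cl)
        v <- c(v, sample(idx, max(1L, round(hyper$validation_fraction * length(idx)))))
      }
      v
    } else sample(n, n_val)
    tr <- setdiff(seq_len(n), val)
    params <- list(
      objective = if (classify) "binary:logistic" else "reg:squarederror",
      max_depth = hyper$max_depth, eta = hyper$learning_rate,
      subsample = hyper$subsample, nthread = 1,
      seed = child_seed(seed, "xgb"))
    dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr])
    dva <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val])
    fit <- xgboost::xgb.train(
      params = params, data = dtr, nrounds = hyper$n_trees,
      evals = list(val = dva),
      early_stopping_rounds = hyper$early_stopping_rounds, verbose = 0)
    best_iter <- xgboost::xgb.attributes(fit)$best_iteration %||% hyper$n_trees
  } else {
    fam <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
    set.seed(child_seed(seed, "foldid"))
    foldid <- sample(rep_len(1:5, n))
    fit <- glmnet::cv.glmnet(x, y, family = fam, alpha = 0, foldid = foldid,
                             standardize = TRUE)
  }
  structure(
    list(kind = kind, fit = fit, best_iter = best_iter, n_features = ncol(x),
         feature_names = colnames(x), seed = as.integer(seed),
         provenance = provenance),
    class = "risk_model"
  )
}

#' @export
predict.risk_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != object$n_features)
    stop_epiprs("expected %d features, got %d", object$n_features, ncol(newx))
  if (object$kind == "linear-penalized") {
    as.numeric(predict(object$fit, newx = newx, s = "lambda.min", type = "response"))
  } else {
    as.numeric(predict(object$fit, xgboost::xgb.DMatrix(newx)))
  }
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model (%s): %d features%s\n", x$kind, x$n_features,
              if (!is.na(x$best_iter)) sprintf(", %s boosting rounds", x$best_iter) else ""))
  invisible(x)
}

#' Area under the ROC curve (rank-based, ties at 1/2)
#'
#' `A = (rank-sum of case scores - n_case (n_case + 1) / 2) /
#' (n_case * n_control)` with average ranks for ties — the Mann-Whitney
#' form of the auROC.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = case); both classes must be present.
#' @return The auROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_epiprs("auROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Relative proportional gain in auROC over random guessing
#'
#' `lambda = (A - 0.5) / 0.5`: 0 for a random-guess predictor, 1 for a
#' perfect one.
#'
#' @param A auROC in `[0, 1]`.
#' @return The lambda index.
#' @export
lambda_index <- function(A) {
  if (any(A < 0 | A > 1)) stop_epiprs("auROC must lie in [0, 1]")
  (A - 0.5) / 0.5
}

#' Optimally weighted combination of per-block models
#'
#' Fits a logistic regression of the training labels on the per-block
#' training scores (intercept included) and applies the fitted linear
#' combination to the test scores. Constant score columns are dropped with
#' a warning.
#'
#' @param train_scores Matrix (train samples x blocks) of per-block scores.
#' @param labels Binary training labels.
#' @param test_scores Matrix (test samples x blocks), same columns.
#' @return A list with `scores` (combined test scores), `weights` (named
#'   coefficients incl. intercept) and `kept` (retained column indices).
#' @export
combine_block_models <- function(train_scores, labels, test_scores) {
  train_scores <- as.matrix(train_scores); test_scores <- as.matrix(test_scores)
  keep <- apply(train_scores, 2, function(col) var(col) > 0)
  if (!any(keep)) stop_epiprs("all per-block score columns are constant")
  if (!all(keep)) warning(sprintf("dropping %d constant score column(s)", sum(!keep)))
  tr <- train_scores[, keep, drop = FALSE]
  te <- test_scores[, keep, drop = FALSE]
  df <- data.frame(y = labels, tr)
  fit <- glm(y ~ ., data = df, family = binomial())
  co <- coef(fit); co[is.na(co)] <- 0
  eta <- cbind(1, te) %*% co
  list(scores = as.numeric(plogis(eta)), weights = co, kept = which(keep))
}

# Fit one method arm of the benchmark on a simulated cohort and return the
# test auROC. Internal.
benchmark_arm <- function(method, sim, split, extractor, d_prime, hyper, seed,
                          common_maf_min = 0.05) {
  cohort <- sim$cohort
  labels <- sim$labels
  tr <- split$train; te <- split$test
  D <- dosage_matrix(cohort)
  scores <- switch(method,
    "linear-baseline" = {
      # stand-in for summary-statistic linear PRS: ridge logistic on
      # standardized common-variant dosages (rare variants excluded, as in
      # the common-SNP linear methods it emulates)
      maf_tr <- colMeans(D[tr, , drop = FALSE]) / 2
      maf_tr <- pmin(maf_tr, 1 - maf_tr)
      keep <- maf_tr >= common_maf_min
      if (!any(keep)) stop_epiprs("no common variants left for the linear baseline")
      mu <- colMeans(D[tr, keep, drop = FALSE])
      sdv <- apply(D[tr, keep, drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1
      std <- function(M) sweep(sweep(M[, keep, drop = FALSE], 2, mu), 2, sdv, "/")
      m <- train_risk_model(std(D[tr, , drop = FALSE]), labels[tr],
                            kind = "linear-penalized", seed = seed)
      predict(m, std(D[te, , drop = FALSE]))
    },
    "genotype-gbrt" = {
      m <- train_risk_model(D[tr, , drop = FALSE], labels[tr],
                            kind = "gbrt-classify", hyper = hyper, seed = seed)
      predict(m, D[te, , drop = FALSE])
    },
    "genotype-pca-gbrt" = {
      mu <- colMeans(D[tr, , drop = FALSE])
      sdv <- apply(D[tr, , drop = FALSE], 2, sd); sdv[sdv == 0] <- 1
      std <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
      pc <- svd(std(D[tr, , drop = FALSE]), nu = 0)
      n_pc <- min(20L, sum(pc$d > 1e-8))
      rot <- pc$v[, seq_len(n_pc), drop = FALSE]
      m <- train_risk_model(std(D[tr, , drop = FALSE]) %*% rot, labels[tr],
                            kind = "gbrt-classify", hyper = hyper, seed = seed)
      predict(m, std(D[te, , drop = FALSE]) %*% rot)
    },
    "epi-prs" = {
      variants <- cohort_to_variants(cohort)
      store <- build_cohort_haplotypes(cohort$references, variants)
      windows <- do.call(rbind, lapply(seq_len(nrow(cohort$blocks)), function(b) {
        w <- tile_block(cohort$blocks[b, ], cohort$cfg$geometry,
                        contig_length = nchar(cohort$references[b]))
        w$block <- cohort$blocks$id[b]
        w
      }))
      feats <- extract_cohort(store, windows, extractor)
      pca <- fit_block_pca(feats, d_prime, train = tr)
      red <- reduce_cohort(feats, pca)
      m <- train_risk_model(red$x[tr, , drop = FALSE], labels[tr],
                            kind = "gbrt-classify", hyper = hyper, seed = seed)
      predict(m, red$x[te, , drop = FALSE])
    },
    stop_epiprs("unknown method '%s'", method))
  auroc(scores, labels[te])
}

#' Benchmark risk-prediction methods on simulated cohorts
#'
#' For each replicate a fresh cohort is simulated from the configuration
#' (sequence-coupled when an extractor is given), one stratified 80/20
#' split is drawn, and every requested method is fitted on the identical
#' training set and scored on the identical test set.
#'
#' Methods: `"epi-prs"` (haplotype sequences -> feature extraction ->
#' per-bin PCA -> GBRT), `"genotype-gbrt"` (GBRT on raw dosages,
#' rare + common), `"genotype-pca-gbrt"` (GBRT on top genotype PCs),
#' `"linear-baseline"` (ridge logistic on standardized common-variant
#' dosages).
#'
#' @param cfg A [sim_config()].
#' @param methods Character vector of method names.
#' @param n_reps Number of replicates.
#' @param extractor A `seq_extractor`; required for `"epi-prs"` and used to
#'   couple the simulation to sequences.
#' @param d_prime Components per bin for the epi-prs arm.
#' @param train_frac Training fraction.
#' @param hyper GBRT hyperparameters.
#' @param master_seed Master seed.
#' @return A data.frame with one row per (method, replicate): `method`,
#'   `replicate`, `auroc`, `lambda`, `n_train`, `n_test`, `test_hash`.
#' @export
run_benchmark <- function(cfg, methods = c("epi-prs", "genotype-gbrt",
                                           "genotype-pca-gbrt", "linear-baseline"),
                          n_reps = 20L, extractor = NULL, d_prime = 5L,
                          train_frac = 0.8, hyper = gbrt_hyperparams(),
                          master_seed = 1L) {
  if ("epi-prs" %in% methods && is.null(extractor))
    stop_epiprs("the epi-prs arm needs an extractor")
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- child_seed(master_seed, paste0("rep", r))
    sim <- regpheno(cfg_r, extractor = extractor)
    split <- split_cohort(sim$labels, frac = train_frac,
                          seed = child_seed(master_seed, paste0("split", r)))
    th <- fnv1a_hash(split$test)
    for (meth in methods) {
      A <- benchmark_arm(meth, sim, split, extractor, d_prime, hyper,
                         seed = child_seed(master_seed, paste0(meth, r)))
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, replicate = r, auroc = A, lambda = lambda_index(A),
        n_train = length(split$train), n_test = length(split$test),
        test_hash = th, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
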