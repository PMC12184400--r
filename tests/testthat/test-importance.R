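# Build a feature_store by hand: values[n, 2, 1, k, d] with optional planted
# signal in one track.
fake_store <- function(n = 200, k = 5, d = 20, signal_track = NULL, seed = 1) {
  set.seed(seed)
  values <- array(rnorm(n * 2 * k * d), dim = c(n, 2, 1, k, d))
  labels <- rbinom(n, 1, 0.5)
  if (!is.null(signal_track)) {
    # recycles n-major over the (n, 2[, k]) slab regardless of k
    values[, , 1, , signal_track] <- values[, , 1, , signal_track] +
      rep(2 * labels, times = 2 * k)
  }
  store <- structure(
    list(values = values, samples = paste0("s", seq_len(n)),
         windows = data.frame(window = 1), labels = paste0("track", seq_len(d)),
         extractor = "fake", n_extract_calls = 0L),
    class = "feature_store")
  list(store = store, labels = labels)
}

test_that("track importance recovers a planted signal track", {
  hits <- 0L
  for (s in 1:20) {
    fx <- fake_store(n = 150, k = 5, d = 20, signal_track = 7, seed = s)
    imp <- track_importance(fx$store, fx$labels,
                            hyper = gbrt_hyperparams(n_trees = 40), seed = s)
    hits <- hits + (which.max(imp) == 7L)
  }
  expect_gte(hits, 18L)
})

test_that("track importance is flat under the null", {
  ok <- 0L
  for (s in 1:20) {
    fx <- fake_store(n = 150, k = 5, d = 20, signal_track = NULL, seed = 100 + s)
    imp <- track_importance(fx$store, fx$labels,
                            hyper = gbrt_hyperparams(n_trees = 40), seed = s)
    ok <- ok + (max(imp) < 3 * median(imp))
  }
  expect_gte(ok, 18L)
})

test_that("single-bin track importance equals that bin's model importances", {
  fx <- fake_store(n = 150, k = 1, d = 10, signal_track = 3, seed = 5)
  imp <- track_importance(fx$store, fx$labels,
                          hyper = gbrt_hyperparams(n_trees = 40), seed = 5)
  x <- (fx$store$values[, 1, 1, 1, ] + fx$store$values[, 2, 1, 1, ]) / 2
  m <- train_risk_model(x, fx$labels, kind = "gbrt-classify",
                        hyper = gbrt_hyperparams(n_trees = 40),
                        seed = epiprs:::child_seed(5, "bin1.1"))
  oracle <- epiprs:::gini_importance(m$fit, 10)
  expect_equal(unname(imp), oracle, tolerance = 1e-12)
  expect_equal(sum(imp), 1, tolerance = 1e-8)
  expect_true(all(imp >= 0))
})

test_that("bin importance is the group mean of PC importances", {
  set.seed(6)
  n <- 300
  map <- data.frame(window = rep(1:2, each = 6),
                    bin = rep(rep(1:3, each = 2), 2),
                    comp = rep(1:2, 6))
  x <- matrix(rnorm(n * 12), n, 12)
  colnames(x) <- paste0("w", map$window, ".b", map$bin, ".pc", map$comp)
  y <- as.integer(x[, 1] + x[, 8] + rnorm(n, sd = 0.5) > 0)
  m <- train_risk_model(x, y, kind = "gbrt-classify",
                        hyper = gbrt_hyperparams(n_trees = 60), seed = 7)
  bi <- bin_importance(m, map)
  expect_equal(nrow(bi), 6L)
  imp <- epiprs:::gini_importance(m$fit, 12, m$feature_names)
  # brute-force grouping oracle
  for (r in seq_len(nrow(bi))) {
    idx <- which(map$window == bi$window[r] & map$bin == bi$bin[r])
    expect_equal(bi$score[r], mean(imp[idx]), tolerance = 1e-12)
  }
  expect_error(bin_importance(m, map[1:5, ]), "partition")
})

test_that("quantile bin sets have the stated sizes and deterministic ties", {
  scores <- runif(19700)
  qs <- quantile_bins(scores, 0.01)
  expect_length(qs$top, 197L)
  expect_length(qs$bottom, 197L)
  expect_length(intersect(qs$top, qs$bottom), 0L)
  small <- quantile_bins(runif(50), 0.01)
  expect_length(small$top, 1L)
  tied <- quantile_bins(rep(1, 10), 0.2)
  expect_equal(tied$top, 1:2)    # ties broken by bin order
  expect_equal(tied$bottom, 1:2)
  expect_error(quantile_bins(scores, 0.7), "between 0 and 0.5")
})

test_that("annotation overlap matches a brute-force all-pairs scan", {
  bins <- data.frame(chrom = "chr1", start = seq(0, 990, by = 10),
                     end = seq(10, 1000, by = 10))
  whole <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(annotation_overlap(bins, whole)$fraction, 1.0)
  far <- data.frame(chrom = "chr1", start = 5000, end = 6000)
  expect_equal(annotation_overlap(bins, far)$fraction, 0.0)
  off_chrom <- data.frame(chrom = "chr2", start = 0, end = 1000)
  expect_equal(annotation_overlap(bins, off_chrom)$fraction, 0.0)

  set.seed(8)
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), 120, TRUE),
                    start = sample(0:950, 120, TRUE))
  rnd$end <- rnd$start + sample(5:60, 120, TRUE)
  rbins <- data.frame(chrom = sample(c("chr1", "chr2"), 80, TRUE),
                      start = sample(0:980, 80, TRUE))
  rbins$end <- rbins$start + 20
  got <- annotation_overlap(rbins, rnd)
  brute <- vapply(seq_len(80), function(i)
    any(rnd$chrom == rbins$chrom[i] & rnd$start < rbins$end[i] &
        rnd$end > rbins$start[i]), TRUE)
  expect_equal(got$hits, brute)
  expect_equal(got$fraction, mean(brute))
  expect_error(annotation_overlap(bins[0, ], whole), "empty")
})

test_that("overlap fractions reproduce the 173-of-197 arithmetic with rules and conditionals", {
  # 197 bins, of which the first 173 intersect the open-chromatin track
  bins <- data.frame(chrom = "chr1", start = (0:196) * 100, end = (0:196) * 100 + 50)
  open <- data.frame(chrom = "chr1", start = 0, end = 172 * 100 + 25)
  res <- annotation_overlap(bins, open)
  expect_equal(res$n_overlap, 173L)
  expect_equal(round(res$fraction, 4), 0.8782)
  # conditional: of the 173 open bins, the first 100 also carry the active mark
  mark <- data.frame(chrom = "chr1", start = 0, end = 99 * 100 + 25)
  res2 <- annotation_overlap(bins, open, second = mark)
  expect_equal(res2$conditional$n_overlap, 100L)
  expect_equal(res2$conditional$n, 173L)
  # rule = "all" needs every track
  both <- annotation_overlap(bins, list(open, mark), rule = "all")
  expect_equal(both$n_overlap, 100L)
  any_rule <- annotation_overlap(bins, list(open, mark), rule = "any")
  expect_equal(any_rule$n_overlap, 173L)
})
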