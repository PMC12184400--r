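test_that("extractor construction is reproducible and validates its arguments", {
  e1 <- test_extractor(seed = 9)
  e2 <- test_extractor(seed = 9)
  s <- random_dna(1024, seed = 1)
  expect_identical(extract_features(e1, s), extract_features(e2, s))
  expect_error(synthetic_extractor(test_geometry(), d = 2, n_motifs = 5), "n_motifs")
  expect_error(synthetic_extractor(test_geometry(), d = 8,
                                   track_labels = rep("x", 8)), "unique")
})

test_that("extraction is deterministic, shape-checked, and defined on all-N input", {
  ex <- test_extractor()
  s <- random_dna(1024, seed = 2)
  f <- extract_features(ex, s)
  expect_equal(dim(f), c(4L, 12L))
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_features(ex, s))
  expect_error(extract_features(ex, substr(s, 1, 500)), "length 500")
  fn <- extract_features(ex, strrep("N", 1024))
  expect_true(all(is.finite(fn)))
  # no motif hits and no GC: the baseline row has zero counts everywhere
  zn <- extract_batch(ex, strrep("N", 1024), raw = TRUE)[[1]]
  expect_true(all(zn == 0))
})

test_that("single-base substitutions only perturb bins within the receptive flank", {
  ex <- test_extractor(flank = 8)  # receptive flank = 8 + 5 - 1 = 12
  cfg <- ex$cfg
  set.seed(31)
  s <- random_dna(1024)
  f0 <- extract_features(ex, s)
  bin_start <- cfg$margin + (seq_len(cfg$n_bins) - 1L) * cfg$bin_size
  bin_end <- bin_start + cfg$bin_size
  for (pos in c(1L, 300L, 400L, 520L, 700L, 790L, 1000L)) {
    chars <- strsplit(s, "")[[1]]
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
    f1 <- extract_features(ex, paste(chars, collapse = ""))
    changed <- which(rowSums(abs(f1 - f0)) > 0)
    allowed <- which(pos - 1L >= bin_start - ex$receptive_flank &
                     pos - 1L < bin_end + ex$receptive_flank)
    expect_true(all(changed %in% allowed),
                info = sprintf("substitution at %d leaked outside its receptive flank", pos))
  }
})

test_that("planting a motif copy raises exactly that bin's count by one", {
  ex <- test_extractor(flank = 8)
  cfg <- ex$cfg
  motif <- ex$motifs[2]
  # poly-A background guarantees zero accidental hits unless the motif is a
  # run of A's (regenerate the extractor if so)
  stopifnot(motif != strrep("A", nchar(motif)))
  base <- strrep("A", 1024)
  z0 <- extract_batch(ex, base, raw = TRUE)[[1]]
  # plant one copy at the center of bin 3
  at <- cfg$margin + 2L * cfg$bin_size + 60L
  planted <- paste0(substr(base, 1, at - 1), motif,
                    substr(base, at + nchar(motif), 1024))
  z1 <- extract_batch(ex, planted, raw = TRUE)[[1]]
  delta <- z1[, 2] - z0[, 2]
  expect_equal(delta[3], 1)
  expect_true(all(delta[-3] %in% c(0, 1)))  # flank-adjacent bins may also see it
  # independent string-count oracle over the extended bin
  lo <- cfg$margin + 2L * cfg$bin_size - ex$flank
  hi <- cfg$margin + 3L * cfg$bin_size + ex$flank
  starts <- gregexpr(motif, planted, fixed = TRUE)[[1]]
  oracle <- sum(starts >= lo + 1L & starts <= hi)
  expect_equal(unname(z1[3, 2]), oracle)
})

test_that("cohort extraction yields 2 tensors per sample-window and caching is transparent", {
  fx <- toy_variants(n_samples = 3, n_sites = 10, contig_len = 1200L, seed = 17)
  ex <- test_extractor()
  refs <- c(chrT = fx$reference)
  # make two samples identical so the cache can deduplicate
  v <- fx$variants
  v$a1[, "s3"] <- v$a1[, "s1"]; v$a2[, "s3"] <- v$a2[, "s1"]
  store <- build_cohort_haplotypes(refs, v)
  windows <- data.frame(window = 1L, chrom = "chrT", input_start = 0L,
                        input_end = 1024L, central_start = 256L,
                        central_end = 768L, shifted = FALSE)
  cached <- extract_cohort(store, windows, ex, cache = TRUE)
  plain <- extract_cohort(store, windows, ex, cache = FALSE)
  expect_equal(dim(cached$values), c(3L, 2L, 1L, 4L, 12L))
  expect_equal(plain$n_extract_calls, 6L)         # 2 * n * l
  expect_lt(cached$n_extract_calls, plain$n_extract_calls)
  expect_identical(cached$values, plain$values)
  expect_identical(cached$values["s1", , 1, , ], cached$values["s3", , 1, , ])
})

test_that("swapping a sample's haplotypes swaps its tensors and nothing else", {
  fx <- toy_variants(n_samples = 2, n_sites = 10, contig_len = 1200L, seed = 23)
  ex <- test_extractor()
  refs <- c(chrT = fx$reference)
  store <- build_cohort_haplotypes(refs, fx$variants)
  windows <- data.frame(window = 1L, chrom = "chrT", input_start = 0L,
                        input_end = 1024L, central_start = 256L,
                        central_end = 768L, shifted = FALSE)
  f1 <- extract_cohort(store, windows, ex)
  swapped <- store
  swapped$chrT$seqs["s1", ] <- swapped$chrT$seqs["s1", 2:1]
  f2 <- extract_cohort(swapped, windows, ex)
  expect_identical(f2$values["s1", 1, , , ], f1$values["s1", 2, , , ])
  expect_identical(f2$values["s1", 2, , , ], f1$values["s1", 1, , , ])
  expect_identical(f2$values["s2", , , , ], f1$values["s2", , , , ])
})

test_that("track selection subsets stably and commutes with extraction", {
  ex <- synthetic_extractor(test_geometry(), d = 6, n_motifs = 3, seed = 2,
    track_labels = c("blood_DNase", "liver_DNase", "blood_CAGE",
                     "brain_CTCF", "liver_CAGE", "blood_H3K27ac"))
  fx <- toy_variants(n_samples = 2, n_sites = 8, contig_len = 1200L, seed = 29)
  store <- build_cohort_haplotypes(c(chrT = fx$reference), fx$variants)
  windows <- data.frame(window = 1L, chrom = "chrT", input_start = 0L,
                        input_end = 1024L, central_start = 256L,
                        central_end = 768L, shifted = FALSE)
  feats <- extract_cohort(store, windows, ex)
  all_kept <- select_tracks(feats, ".")
  expect_identical(all_kept$values, feats$values)
  blood <- select_tracks(feats, "blood")
  expect_equal(blood$labels, c("blood_DNase", "blood_CAGE", "blood_H3K27ac"))
  expect_identical(unname(blood$values[, , , , ]),
                   unname(feats$values[, , , , feats$labels %in% blood$labels]))
  expect_error(select_tracks(feats, "kidney"), "no labels")
})
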