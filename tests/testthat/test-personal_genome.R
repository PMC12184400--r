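test_that("filter_snvs keeps only bi-allelic SNVs and drops indels", {
  records <- list(
    sites = data.frame(
      chrom = "chr1", pos = c(10L, 20L, 30L),
      id = c("snp", "del", "ins"),
      ref = c("A", "AT", "G"), alt = c("C", "A", "GTT"),
      stringsAsFactors = FALSE),
    gt = matrix(c("0|1", "0|0", "1|1"), 3, 2,
                dimnames = list(NULL, c("s1", "s2")))
  )
  out <- filter_snvs(records)
  expect_equal(nrow(out$sites), 1L)
  expect_equal(out$sites$id, "snp")
  expect_equal(out$a1[1, ], c(s1 = 0L, s2 = 0L))
  expect_equal(out$a2[1, ], c(s1 = 1L, s2 = 1L))

  empty <- filter_snvs(list(
    sites = records$sites[0, ], gt = records$gt[0, , drop = FALSE]))
  expect_equal(nrow(empty$sites), 0L)
})

test_that("multi-allelic SNVs split into bi-allelic records with consistent indicators", {
  # all 9 diploid genotype combinations over alleles {0, 1, 2}
  combos <- expand.grid(a = 0:2, b = 0:2)
  gt <- matrix(paste0(combos$a, "|", combos$b), nrow = 1)
  colnames(gt) <- paste0("s", seq_len(nrow(combos)))
  records <- list(
    sites = data.frame(chrom = "chr1", pos = 100L, id = "m", ref = "A",
                       alt = "C,G", stringsAsFactors = FALSE),
    gt = gt)
  out <- filter_snvs(records)
  expect_equal(nrow(out$sites), 2L)
  expect_equal(out$sites$alt, c("C", "G"))
  # per-sample indicator sums across the split records equal the non-ref
  # allele count of the original genotype
  nonref <- (combos$a != 0) + (combos$b != 0)
  expect_equal(unname(colSums(out$a1 + out$a2)), nonref)
  # each split record carries only its own alt allele
  alt1 <- (combos$a == 1) + (combos$b == 1)
  expect_equal(unname(out$a1[1, ] + out$a2[1, ]), alt1)
})

test_that("unphased genotypes error; missing genotypes become hom-ref with a warning", {
  records <- list(
    sites = data.frame(chrom = "chr1", pos = 10L, id = "v", ref = "A",
                       alt = "C", stringsAsFactors = FALSE),
    gt = matrix(c("0/1", "0|0"), 1, 2, dimnames = list(NULL, c("s1", "s2"))))
  expect_error(filter_snvs(records), "unphased.*s1.*chr1:10")

  records$gt <- matrix(c("./.", "1|1"), 1, 2, dimnames = list(NULL, c("s1", "s2")))
  expect_warning(out <- filter_snvs(records), "missing genotypes")
  expect_equal(out$n_missing, 1L)
  expect_equal(unname(out$a1[1, ]), c(0L, 1L))
})

test_that("haplotype construction substitutes phased alleles and nothing else", {
  fx <- toy_variants()
  region <- list(chrom = "chrT", start = 0L, end = 1000L)
  v <- fx$variants

  # homozygous reference sample: both sequences equal the reference
  v0 <- v; v0$a1[, "s1"] <- 0L; v0$a2[, "s1"] <- 0L
  hp <- build_haplotypes(fx$reference, v0, "s1", region)
  expect_identical(hp$hap1, fx$reference)
  expect_identical(hp$hap2, fx$reference)

  # single het site phased 0|1
  v1 <- v0
  v1$a2[5, "s1"] <- 1L
  hp <- build_haplotypes(fx$reference, v1, "s1", region)
  p <- v$sites$pos[5]
  expect_identical(hp$hap1, fx$reference)
  expect_identical(substring(hp$hap2, p, p), v$sites$alt[5])
  expect_identical(substring(hp$hap2, 1, p - 1), substring(fx$reference, 1, p - 1))
})

test_that("round-trip: base-wise diff of haplotypes recovers the phased genotypes", {
  fx <- toy_variants(n_samples = 5, n_sites = 20, seed = 11)
  region <- list(chrom = "chrT", start = 0L, end = 1000L)
  ref_chars <- strsplit(fx$reference, "")[[1]]
  for (s in fx$variants$samples) {
    hp <- build_haplotypes(fx$reference, fx$variants, s, region)
    expect_equal(nchar(hp$hap1), 1000L)
    for (h in 1:2) {
      hap_chars <- strsplit(if (h == 1) hp$hap1 else hp$hap2, "")[[1]]
      diffs <- which(hap_chars != ref_chars)
      amat <- if (h == 1) fx$variants$a1 else fx$variants$a2
      carried <- fx$variants$sites$pos[amat[, s] == 1L]
      expect_equal(diffs, carried)
      expect_true(all(hap_chars[diffs] ==
        fx$variants$sites$alt[match(diffs, fx$variants$sites$pos)]))
    }
  }
})

test_that("reference mismatch at a variant position is an error", {
  fx <- toy_variants()
  region <- list(chrom = "chrT", start = 0L, end = 1000L)
  v <- fx$variants
  v$sites$ref[3] <- setdiff(c("A", "C", "G", "T"),
                            c(v$sites$ref[3], v$sites$alt[3]))[1]
  expect_error(build_haplotypes(fx$reference, v, "s1", region),
               "reference mismatch")
})

test_that("locality: one genotype change moves at most one base of that sample only", {
  fx <- toy_variants(n_samples = 3, n_sites = 10, seed = 21)
  refs <- c(chrT = fx$reference)
  before <- build_cohort_haplotypes(refs, fx$variants)
  v2 <- fx$variants
  v2$a1[4, "s2"] <- 1L - v2$a1[4, "s2"]
  after <- build_cohort_haplotypes(refs, v2)
  for (s in fx$variants$samples) for (h in 1:2) {
    d <- sum(strsplit(before$chrT$seqs[s, h], "")[[1]] !=
             strsplit(after$chrT$seqs[s, h], "")[[1]])
    expect_equal(d, as.integer(s == "s2" && h == 1L))
  }
})

test_that("cohort store matches the per-sample constructor and FASTA export round-trips", {
  fx <- toy_variants(n_samples = 3, n_sites = 12, seed = 8)
  refs <- c(chrT = fx$reference)
  store <- build_cohort_haplotypes(refs, fx$variants)
  region <- list(chrom = "chrT", start = 0L, end = 1000L)
  hp <- build_haplotypes(fx$reference, fx$variants, "s2", region)
  expect_identical(store$chrT$seqs["s2", 1], hp$hap1)
  expect_identical(store$chrT$seqs["s2", 2], hp$hap2)

  path <- tempfile(fileext = ".fa")
  write_haplotype_fasta(store, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(length(back), 6L)
  expect_identical(as.character(back[["s2_hap1"]]), hp$hap1)
})

test_that("phased VCF writing round-trips through the VCF reader", {
  fx <- toy_variants(n_samples = 4, n_sites = 15, seed = 13)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(fx$variants, path, contig_lengths = c(chrT = 1000L))
  back <- filter_snvs(read_phased_vcf(path))
  expect_equal(back$sites$pos, fx$variants$sites$pos)
  expect_equal(unname(back$a1), unname(fx$variants$a1))
  expect_equal(unname(back$a2), unname(fx$variants$a2))
})
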