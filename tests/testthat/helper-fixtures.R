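# Shared deterministic fixtures, built in code at load time. Small geometry
# (1 kb inputs, 4 bins) for unit tests; the benchmark geometry (4 kb, 16
# bins) lives in the acceptance suite.

test_geometry <- function() window_config(1024L, 4L, 128L)

test_extractor <- function(d = 12L, flank = 8L, seed = 5L) {
  synthetic_extractor(test_geometry(), d = d, n_motifs = 4L,
                      flank = flank, motif_length = 5L, seed = seed)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small phased variant table over one contig, built by hand.
toy_variants <- function(n_samples = 4, n_sites = 20, contig = "chrT",
                         contig_len = 1000L, seed = 3) {
  set.seed(seed)
  pos <- sort(sample(contig_len, n_sites))
  ref_seq <- random_dna(contig_len)
  refb <- substring(ref_seq, pos, pos)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  samples <- paste0("s", seq_len(n_samples))
  a1 <- matrix(rbinom(n_sites * n_samples, 1, 0.4), n_sites, n_samples,
               dimnames = list(NULL, samples))
  a2 <- matrix(rbinom(n_sites * n_samples, 1, 0.4), n_sites, n_samples,
               dimnames = list(NULL, samples))
  list(
    reference = ref_seq,
    variants = structure(
      list(sites = data.frame(chrom = contig, pos = pos,
                              id = paste0("v", seq_len(n_sites)),
                              ref = refb, alt = altb, stringsAsFactors = FALSE),
           a1 = a1, a2 = a2, samples = samples, n_missing = 0L),
      class = "phased_variants")
  )
}

# Memoized tiny simulated dataset shared across test files.
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("tiny", seed = 1L)
    cache
  }
})
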