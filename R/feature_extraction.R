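#' Construct a deterministic synthetic sequence-to-feature extractor
#'
#' Stands in for a pretrained genomic sequence model behind the same
#' contract: a nucleotide sequence of `cfg$input_length` bp in, a
#' `n_bins x d` matrix of feature-track values out. Per bin the extractor
#' counts occurrences (by start position) of `n_motifs` fixed consensus
#' motifs within the bin extended by `flank` bp on each side, appends the GC
#' fraction and the 16 dinucleotide frequencies of the extended bin, and
#' maps this `(n_motifs + 17)`-vector through a fixed seeded linear
#' projection followed by a softplus nonlinearity. The composition channels
#' make the response to a substitution context-specific (a pretrained
#' sequence model likewise responds to any local sequence change, not only
#' to motif gain/loss), while the motif channels make regulatory disruption
#' directly visible. Variant effects on the output are local and sparse: a
#' base substitution can only perturb bins within
#' `flank + motif_length - 1` bp of the base (the `receptive_flank`).
#'
#' Motifs and the projection are drawn reproducibly from `seed`, so two
#' constructions with identical arguments are bit-identical extractors.
#'
#' @param cfg A [window_config()] fixing the input geometry.
#' @param d Number of output feature tracks.
#' @param n_motifs Number of consensus motifs (must be `<= d`).
#' @param flank Flank in bp added to each side of a bin when counting
#'   motifs and computing GC.
#' @param motif_length Length of each consensus motif in bp.
#' @param seed Integer seed for motif and projection generation.
#' @param track_labels Optional character vector of `d` unique track labels;
#'   defaults to generated `<tissue>_<assay>_<i>` labels.
#' @return An object of class `seq_extractor`.
#' @export
synthetic_extractor <- function(cfg, d = 24L, n_motifs = 6L, flank = 32L,
                                motif_length = 8L, seed = 1L,
                                track_labels = NULL) {
  d <- as.integer(d); n_motifs <- as.integer(n_motifs)
  if (n_motifs < 1L || d < n_motifs)
    stop_epiprs("need d >= n_motifs >= 1 (got d=%d, n_motifs=%d)", d, n_motifs)
  set.seed(child_seed(seed, "motifs"))
  bases <- c("A", "C", "G", "T")
  motifs <- character(0)
  while (length(motifs) < n_motifs) {
    m <- paste(sample(bases, motif_length, replace = TRUE), collapse = "")
    if (!(m %in% motifs)) motifs <- c(motifs, m)
  }
  p <- n_motifs + 17L  # motif counts + GC + 16 dinucleotide frequencies
  set.seed(child_seed(seed, "projection"))
  W <- matrix(rnorm(p * d, sd = 1 / sqrt(p)), p, d)
  b <- rnorm(d, sd = 0.1)
  if (is.null(track_labels)) {
    tissues <- c("blood", "liver", "pancreas", "brain", "muscle", "lung")
    assays <- c("DNase", "CAGE", "H3K27ac", "H3K4me3", "CTCF")
    grid <- expand.grid(assay = assays, tissue = tissues, stringsAsFactors = FALSE)
    track_labels <- paste(grid$tissue, grid$assay, seq_len(nrow(grid)), sep = "_")
    track_labels <- rep_len(track_labels, d)
    track_labels <- make.unique(track_labels, sep = "_")
  }
  if (length(track_labels) != d || anyDuplicated(track_labels))
    stop_epiprs("track_labels must be %d unique strings", d)
  structure(
    list(name = sprintf("synthetic-d%d-m%d-s%d", d, n_motifs, as.integer(seed)),
         cfg = cfg, d = d, motifs = motifs, flank = as.integer(flank),
         motif_length = as.integer(motif_length),
         receptive_flank = as.integer(flank) + as.integer(motif_length) - 1L,
         W = W, b = b, labels = track_labels, seed = as.integer(seed)),
    class = "seq_extractor"
  )
}

#' @export
print.seq_extractor <- function(x, ...) {
  cat(sprintf("seq_extractor '%s': %d tracks, %d motifs of %d bp, flank %d bp (receptive flank %d bp)\n",
              x$name, x$d, length(x$motifs), x$motif_length, x$flank, x$receptive_flank))
  invisible(x)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Extended-bin boundaries in 1-based sequence coordinates.
extractor_bin_bounds <- function(extractor) {
  cfg <- extractor$cfg
  bin_start0 <- cfg$margin + (seq_len(cfg$n_bins) - 1L) * cfg$bin_size
  list(lo = bin_start0 - extractor$flank + 1L,
       hi = bin_start0 + cfg$bin_size + extractor$flank)
}

#' Extract feature values from one input sequence
#'
#' @param extractor A `seq_extractor`.
#' @param sequence Nucleotide string of exactly `cfg$input_length` bp over
#'   the alphabet `{A, C, G, T, N}`.
#' @return A `n_bins x d` numeric matrix (tracks in columns, labelled).
#' @export
extract_features <- function(extractor, sequence) {
  extract_batch(extractor, as.character(sequence))[[1]]
}

#' Extract feature values from a batch of input sequences
#'
#' Vectorized form of [extract_features()]; all sequences share the
#' extractor geometry. The batch is concatenated into one subject so motif
#' matching, GC counting and the projection each run as a single
#' vectorized pass.
#'
#' @param extractor A `seq_extractor`.
#' @param sequences Character vector (or `DNAStringSet`) of input sequences.
#' @param raw If `TRUE`, return the pre-projection per-bin vectors (motif
#'   counts, GC, dinucleotide frequencies) instead of the projected tracks.
#' @return A list of `n_bins x d` matrices, one per sequence (or
#'   `n_bins x (n_motifs + 17)` pre-projection matrices with `raw = TRUE`).
#' @export
extract_batch <- function(extractor, sequences, raw = FALSE) {
  cfg <- extractor$cfg
  seqs <- toupper(as.character(sequences))
  lens <- nchar(seqs)
  if (any(lens != cfg$input_length))
    stop_epiprs("sequence length %d != expected input length %d",
                lens[which(lens != cfg$input_length)[1]], cfg$input_length)
  L <- cfg$input_length
  ns <- length(seqs)
  nm <- length(extractor$motifs)
  k <- cfg$n_bins
  bs <- cfg$bin_size
  fl <- extractor$flank
  ml <- extractor$motif_length
  big <- Biostrings::DNAString(paste(seqs, collapse = ""))
  counts <- matrix(0, ns * k, nm)
  for (mi in seq_len(nm)) {
    st <- Biostrings::start(Biostrings::matchPattern(extractor$motifs[mi], big,
                                                     fixed = TRUE))
    if (length(st) == 0L) next
    si <- (st - 1L) %/% L          # 0-based sequence index
    o <- st - si * L               # 1-based offset within the sequence
    ok <- o <= L - ml + 1L         # drop matches spanning a junction
    si <- si[ok]; o <- o[ok]
    if (length(o) == 0L) next
    # bins whose extended interval [margin+(j-1)bs-fl+1, margin+j*bs+fl]
    # contains the match start o
    jmin <- pmax(1L, as.integer(ceiling((o - cfg$margin - fl) / bs)))
    jmax <- pmin(k, (o - 1L - cfg$margin + fl) %/% bs + 1L)
    keep <- jmax >= jmin
    if (!any(keep)) next
    si <- si[keep]; jmin <- jmin[keep]; jmax <- jmax[keep]
    nrep <- jmax - jmin + 1L
    bins <- sequence(nrep, from = jmin)
    rows <- rep(si * k, nrep) + bins
    counts[, mi] <- tabulate(rows, nbins = ns * k)
  }
  # GC fraction of the clipped extended bins, one Views pass over the batch
  bin_start0 <- cfg$margin + (seq_len(k) - 1L) * bs
  gclo <- pmax(bin_start0 - fl + 1L, 1L)
  gchi <- pmin(bin_start0 + bs + fl, L)
  offs <- rep((seq_len(ns) - 1L) * L, each = k)
  v <- Biostrings::Views(big, start = offs + rep(gclo, ns), end = offs + rep(gchi, ns))
  width <- rep(gchi - gclo + 1L, ns)
  gc <- Biostrings::letterFrequency(v, "GC")[, 1] / width
  dinuc <- Biostrings::oligonucleotideFrequency(v, width = 2L) / (width - 1L)
  Z <- cbind(counts, gc, dinuc)
  colnames(Z) <- c(paste0("motif", seq_len(nm)), "gc", colnames(dinuc))
  if (raw)
    return(lapply(seq_len(ns), function(si)
      Z[(si - 1L) * k + seq_len(k), , drop = FALSE]))
  Fm <- softplus(sweep(Z %*% extractor$W, 2, extractor$b, "+"))
  lapply(seq_len(ns), function(si) {
    m <- Fm[(si - 1L) * k + seq_len(k), , drop = FALSE]
    colnames(m) <- extractor$labels
    m
  })
}

#' Extract features across a cohort of haplotypes
#'
#' Runs the extractor over every (sample, haplotype, window) input sequence
#' and assembles a feature store. With `cache = TRUE`, identical haplotype
#' sequences are extracted only once (memoization); results are identical
#' with and without caching.
#'
#' @param store A `haplotype_store` from [build_cohort_haplotypes()].
#' @param windows A data.frame of windows (as from [tile_block()], with a
#'   `chrom` column naming contigs present in `store`; a `block` column is
#'   carried through if present).
#' @param extractor A `seq_extractor`.
#' @param cache Logical; deduplicate identical sequences before extraction.
#' @return An object of class `feature_store`: list with `values` (numeric
#'   array `[n_samples, 2, n_windows, n_bins, d]`), `samples`, `windows`,
#'   `labels`, `extractor` (name) and `n_extract_calls` (number of extractor
#'   invocations actually performed).
#' @export
extract_cohort <- function(store, windows, extractor, cache = TRUE) {
  cfg <- extractor$cfg
  samples <- rownames(store[[1]]$seqs)
  n <- length(samples); W <- nrow(windows); k <- cfg$n_bins; d <- extractor$d
  # gather all input sequences
  keys <- character(n * 2 * W)
  dim(keys) <- c(n, 2, W)
  for (w in seq_len(W)) {
    chrom <- windows$chrom[w]
    if (is.null(store[[chrom]]))
      stop_epiprs("no haplotype sequences for contig %s (window %d)", chrom, w)
    region <- store[[chrom]]$region
    a <- windows$input_start[w] - region$start
    bz <- windows$input_end[w] - region$start
    if (a < 0 || bz > region$end - region$start)
      stop_epiprs("window %d [%d,%d) not covered by sequences for %s",
                  w, windows$input_start[w], windows$input_end[w], chrom)
    seqs <- store[[chrom]]$seqs
    keys[, 1, w] <- substr(seqs[, 1], a + 1L, bz)
    keys[, 2, w] <- substr(seqs[, 2], a + 1L, bz)
  }
  flat <- as.vector(keys)
  if (cache) {
    uniq <- unique(flat)
    mats <- extract_batch(extractor, uniq)
    idx <- match(flat, uniq)
    calls <- length(uniq)
  } else {
    mats <- extract_batch(extractor, flat)
    idx <- seq_along(flat)
    calls <- length(flat)
  }
  values <- array(NA_real_, dim = c(n, 2, W, k, d),
                  dimnames = list(samples, c("hap1", "hap2"), NULL, NULL, extractor$labels))
  pos <- 1L
  for (w in seq_len(W)) for (h in 1:2) for (s in seq_len(n)) {
    # flat order follows as.vector of [n, 2, W]: sample fastest, then hap, then window
    values[s, h, w, , ] <- mats[[idx[(w - 1L) * 2L * n + (h - 1L) * n + s]]]
    pos <- pos + 1L
  }
  structure(
    list(values = values, samples = samples, windows = windows,
         labels = extractor$labels, extractor = extractor$name,
         n_extract_calls = calls),
    class = "feature_store"
  )
}

#' @export
print.feature_store <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("feature_store: %d samples x 2 haplotypes x %d windows x %d bins x %d tracks (extractor %s)\n",
              dm[1], dm[3], dm[4], dm[5], x$extractor))
  invisible(x)
}

#' Subset a feature store to tracks matching a label predicate
#'
#' @param features A `feature_store`.
#' @param predicate Either a regular expression matched against track labels
#'   or a function mapping the label vector to a logical vector.
#' @return A `feature_store` with the matching tracks, in stable order.
#' @export
select_tracks <- function(features, predicate) {
  keep <- if (is.function(predicate)) predicate(features$labels)
          else grepl(predicate, features$labels)
  if (!any(keep)) stop_epiprs("track predicate matches no labels")
  out <- features
  out$values <- features$values[, , , , keep, drop = FALSE]
  out$labels <- features$labels[keep]
  out
}
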