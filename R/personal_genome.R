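#' Read phased genotypes from a VCF file
#'
#' Parses a plain or bgzipped VCF and returns the raw variant table expected
#' by [filter_snvs()]: site fields plus the per-sample GT strings. No
#' filtering happens here.
#'
#' @param path Path to a VCF file.
#' @return A list with `sites` (data.frame: `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`) and `gt` (sites x samples character matrix of GT fields).
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_epiprs("VCF %s has no GT field", path)
  # vcfR collapses to a vector for a single site
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  rownames(gt) <- NULL
  list(sites = sites, gt = gt)
}

#' Filter a variant table down to phased bi-allelic SNVs
#'
#' Drops insertions and deletions, splits multi-allelic SNV records into
#' bi-allelic records (each carrying the per-sample indicator for its own
#' alternate allele), and converts the GT strings into two phased allele
#' matrices. Retained records must be phased (`|` separator) in every
#' sample; an unphased genotype at a retained site is an error, since
#' phasing is a precondition of the whole workflow. Missing genotypes
#' (`./.` or `.|.`) are treated as homozygous reference and counted in a
#' warning.
#'
#' @param records A list as returned by [read_phased_vcf()]: `sites`
#'   data.frame and `gt` character matrix.
#' @return An object of class `phased_variants`: list with `sites`
#'   (data.frame `chrom`, `pos`, `id`, `ref`, `alt`, sorted by (chrom, pos),
#'   no duplicated (chrom, pos, alt)), `a1` and `a2` (sites x samples 0/1
#'   integer matrices: first and second phased allele), `samples`, and
#'   `n_missing` (count of genotypes imputed to homozygous reference).
#' @export
filter_snvs <- function(records) {
  sites <- records$sites
  gt <- records$gt
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("sample_", seq_len(ncol(gt)))
  bases <- c("A", "C", "G", "T")
  out_sites <- vector("list", nrow(sites))
  out_a1 <- vector("list", nrow(sites))
  out_a2 <- vector("list", nrow(sites))
  n_missing <- 0L
  for (r in seq_len(nrow(sites))) {
    ref <- sites$ref[r]
    if (nchar(ref) != 1L || !(ref %in% bases)) next
    alts <- strsplit(sites$alt[r], ",", fixed = TRUE)[[1]]
    snv_alts <- alts[nchar(alts) == 1L & alts %in% bases & alts != ref]
    if (length(snv_alts) == 0L) next
    g <- gt[r, ]
    miss <- is.na(g) | g %in% c("./.", ".|.", ".")
    n_missing <- n_missing + sum(miss)
    g[miss] <- "0|0"
    unphased <- grepl("/", g, fixed = TRUE)
    if (any(unphased)) {
      j <- which(unphased)[1]
      stop_epiprs("unphased genotype '%s' for sample %s at %s:%d",
                  g[j], samples[j], sites$chrom[r], sites$pos[r])
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    al1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    al2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(al1) || anyNA(al2)) {
      j <- which(is.na(al1) | is.na(al2))[1]
      stop_epiprs("malformed genotype '%s' for sample %s at %s:%d",
                  gt[r, j], samples[j], sites$chrom[r], sites$pos[r])
    }
    for (a in seq_along(alts)) {
      if (!(alts[a] %in% snv_alts)) next
      out_sites[[length(out_sites) + 1L]] <- data.frame(
        chrom = sites$chrom[r], pos = sites$pos[r], id = sites$id[r],
        ref = ref, alt = alts[a], stringsAsFactors = FALSE
      )
      out_a1[[length(out_a1) + 1L]] <- as.integer(al1 == a)
      out_a2[[length(out_a2) + 1L]] <- as.integer(al2 == a)
    }
  }
  keep <- !vapply(out_sites, is.null, TRUE)
  if (!any(keep)) {
    res <- list(
      sites = data.frame(chrom = character(), pos = integer(), id = character(),
                         ref = character(), alt = character(), stringsAsFactors = FALSE),
      a1 = matrix(integer(), 0, length(samples), dimnames = list(NULL, samples)),
      a2 = matrix(integer(), 0, length(samples), dimnames = list(NULL, samples)),
      samples = samples, n_missing = n_missing
    )
    return(structure(res, class = "phased_variants"))
  }
  sites_out <- do.call(rbind, out_sites[keep])
  a1 <- do.call(rbind, out_a1[keep])
  a2 <- do.call(rbind, out_a2[keep])
  ord <- order(sites_out$chrom, sites_out$pos, sites_out$alt)
  sites_out <- sites_out[ord, , drop = FALSE]
  a1 <- a1[ord, , drop = FALSE]; a2 <- a2[ord, , drop = FALSE]
  dup <- duplicated(sites_out[, c("chrom", "pos", "alt")])
  if (any(dup)) {
    sites_out <- sites_out[!dup, , drop = FALSE]
    a1 <- a1[!dup, , drop = FALSE]; a2 <- a2[!dup, , drop = FALSE]
  }
  rownames(sites_out) <- NULL
  colnames(a1) <- samples; colnames(a2) <- samples
  if (n_missing > 0)
    warning(sprintf("%d missing genotypes treated as homozygous reference", n_missing))
  structure(
    list(sites = sites_out, a1 = a1, a2 = a2, samples = samples, n_missing = n_missing),
    class = "phased_variants"
  )
}

#' @export
print.phased_variants <- function(x, ...) {
  cat(sprintf("phased_variants: %d bi-allelic SNVs x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Build the two haplotype sequences of one sample over a region
#'
#' Substitutes the alternate base at every variant position carried on each
#' phased allele. The first phased allele fills the first ("hap1") slot and
#' the second allele the second slot; with statistical phasing the
#' maternal/paternal labels are arbitrary, and downstream reduction is
#' invariant to the order.
#'
#' @param reference Reference sequence for the region (character string or
#'   `Biostrings::DNAString`), uppercase.
#' @param variants A `phased_variants` object restricted to the region.
#' @param sample Sample id (must be a column of the allele matrices).
#' @param region A list with `chrom`, `start`, `end` (0-based half-open);
#'   variant positions (1-based) must satisfy `start < pos <= end`.
#' @return An object of class `haplotype_pair`: list with `sample`, `region`
#'   and `hap1`, `hap2` character sequences of the region length.
#' @export
build_haplotypes <- function(reference, variants, sample, region) {
  refstr <- toupper(as.character(reference))
  reg_len <- region$end - region$start
  if (nchar(refstr) != reg_len)
    stop_epiprs("reference length %d != region length %d", nchar(refstr), reg_len)
  if (!(sample %in% colnames(variants$a1)))
    stop_epiprs("unknown sample '%s'", sample)
  sites <- variants$sites
  onchrom <- sites$chrom == region$chrom
  pos0 <- sites$pos - 1L - region$start  # 0-based offset within region
  inreg <- onchrom & pos0 >= 0L & pos0 < reg_len
  if (any(onchrom & !inreg))
    stop_epiprs("variant at %s:%d falls outside the region",
                region$chrom, sites$pos[which(onchrom & !inreg)[1]])
  chars <- strsplit(refstr, "", fixed = TRUE)[[1]]
  idx <- which(inreg)
  if (length(idx)) {
    at <- pos0[idx] + 1L
    refbase <- chars[at]
    bad <- refbase != sites$ref[idx]
    if (any(bad)) {
      j <- idx[bad][1]
      stop_epiprs("reference mismatch at %s:%d: sequence has '%s', variant ref is '%s'",
                  sites$chrom[j], sites$pos[j], chars[pos0[j] + 1L], sites$ref[j])
    }
    h1 <- chars; h2 <- chars
    sub1 <- variants$a1[idx, sample] == 1L
    sub2 <- variants$a2[idx, sample] == 1L
    h1[at[sub1]] <- sites$alt[idx][sub1]
    h2[at[sub2]] <- sites$alt[idx][sub2]
  } else {
    h1 <- chars; h2 <- chars
  }
  structure(
    list(sample = sample, region = region,
         hap1 = paste(h1, collapse = ""), hap2 = paste(h2, collapse = "")),
    class = "haplotype_pair"
  )
}

#' @export
print.haplotype_pair <- function(x, ...) {
  cat(sprintf("haplotype_pair: sample %s, %s:%d-%d (%d bp)\n", x$sample,
              x$region$chrom, x$region$start, x$region$end, nchar(x$hap1)))
  invisible(x)
}

#' Build haplotype sequences for a whole cohort
#'
#' Applies [build_haplotypes()] to every sample over every contig region,
#' returning an in-memory store consumed by [extract_cohort()].
#'
#' @param references Named character vector (or `DNAStringSet`) of reference
#'   sequences, one per contig; each sequence covers the stored region.
#' @param variants A `phased_variants` object.
#' @param regions A data.frame with `chrom`, `start`, `end` giving the
#'   covered region of each contig (defaults to the whole reference
#'   sequence starting at 0).
#' @return An object of class `haplotype_store`: per contig, a list with
#'   `region` and `seqs`, a samples x 2 character matrix of sequences.
#' @export
build_cohort_haplotypes <- function(references, variants, regions = NULL) {
  refs <- vapply(as.character(references), toupper, "")
  names(refs) <- names(references)
  if (is.null(regions)) {
    regions <- data.frame(chrom = names(refs), start = 0L,
                          end = nchar(refs), stringsAsFactors = FALSE)
  }
  sites <- variants$sites
  store <- list()
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    region <- list(chrom = chrom, start = regions$start[i], end = regions$end[i])
    refstr <- refs[[chrom]]
    reg_len <- region$end - region$start
    if (nchar(refstr) != reg_len)
      stop_epiprs("reference length %d != region length %d for %s",
                  nchar(refstr), reg_len, chrom)
    onchrom <- sites$chrom == chrom
    pos0 <- sites$pos - 1L - region$start
    inreg <- onchrom & pos0 >= 0L & pos0 < reg_len
    if (any(onchrom & !inreg))
      stop_epiprs("variant at %s:%d falls outside the region",
                  chrom, sites$pos[which(onchrom & !inreg)[1]])
    idx <- which(inreg)
    ref_raw <- charToRaw(refstr)
    at <- pos0[idx] + 1L
    bad <- rawToChar(ref_raw[at], multiple = TRUE) != sites$ref[idx]
    if (any(bad)) {
      j <- idx[bad][1]
      stop_epiprs("reference mismatch at %s:%d: sequence has '%s', variant ref is '%s'",
                  chrom, sites$pos[j], substr(refstr, pos0[j] + 1L, pos0[j] + 1L),
                  sites$ref[j])
    }
    alt_raw <- as.raw(vapply(sites$alt[idx], function(a) utf8ToInt(a), 0L))
    seqs <- matrix("", nrow = length(variants$samples), ncol = 2,
                   dimnames = list(variants$samples, c("hap1", "hap2")))
    for (s in seq_along(variants$samples)) {
      r1 <- ref_raw; r2 <- ref_raw
      sub1 <- variants$a1[idx, s] == 1L
      sub2 <- variants$a2[idx, s] == 1L
      r1[at[sub1]] <- alt_raw[sub1]
      r2[at[sub2]] <- alt_raw[sub2]
      seqs[s, 1] <- rawToChar(r1); seqs[s, 2] <- rawToChar(r2)
    }
    store[[chrom]] <- list(region = region, seqs = seqs)
  }
  structure(store, class = "haplotype_store")
}

#' Write a haplotype store as per-sample two-record FASTA
#'
#' Headers are `<sample>_hap1` and `<sample>_hap2`, suffixed with the contig
#' when the store holds several contigs.
#'
#' @param store A `haplotype_store`.
#' @param path Output FASTA path.
#' @export
write_haplotype_fasta <- function(store, path) {
  seqs <- character(0)
  multi <- length(store) > 1
  for (chrom in names(store)) {
    m <- store[[chrom]]$seqs
    for (s in rownames(m)) {
      tag <- if (multi) paste0("_", chrom) else ""
      seqs[paste0(s, "_hap1", tag)] <- m[s, 1]
      seqs[paste0(s, "_hap2", tag)] <- m[s, 2]
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
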