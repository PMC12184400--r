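#' Convert a simulated cohort to a phased variant table
#'
#' @param cohort A `regpheno_cohort`.
#' @return A `phased_variants` object (sites x samples allele matrices).
#' @export
cohort_to_variants <- function(cohort) {
  sites <- cohort$sites[, c("chrom", "pos", "id", "ref", "alt")]
  rownames(sites) <- NULL
  structure(
    list(sites = sites, a1 = t(cohort$H1), a2 = t(cohort$H2),
         samples = cohort$samples, n_missing = 0L),
    class = "phased_variants"
  )
}

#' Write a phased variant table as VCF
#'
#' Emits a minimal VCFv4.2 with contig headers and phased GT fields,
#' readable back through [read_phased_vcf()].
#'
#' @param variants A `phased_variants` object.
#' @param path Output path (plain text).
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @export
write_phased_vcf <- function(variants, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (chrom in unique(variants$sites$chrom)) {
    len <- contig_lengths[chrom]
    writeLines(if (!is.null(contig_lengths) && !is.na(len))
      sprintf("##contig=<ID=%s,length=%d>", chrom, len)
      else sprintf("##contig=<ID=%s>", chrom), con)
  }
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", variants$samples), collapse = "\t"), con)
  gts <- matrix(paste0(variants$a1, "|", variants$a2), nrow = nrow(variants$sites))
  lines <- apply(cbind(variants$sites$chrom, variants$sites$pos, variants$sites$id,
                       variants$sites$ref, variants$sites$alt, ".", "PASS", ".",
                       "GT", gts), 1, paste, collapse = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write reference contigs as FASTA
#'
#' @param references Named character vector of contig sequences.
#' @param path Output path.
#' @export
write_reference_fasta <- function(references, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(references), path)
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Produces everything the prediction pipeline needs to run on its own
#' output: reference FASTA, phased VCF, block BED, phenotype TSV,
#' regulatory-element BED, causal-gene TSV, TF-binding matrix TSV, and a
#' JSON manifest recording the configuration, its hash and the seeds.
#'
#' @param sim A `regpheno_sim`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sim$cohort
  write_reference_fasta(cohort$references, file.path(dir, "reference.fa"))
  write_phased_vcf(cohort_to_variants(cohort), file.path(dir, "genotypes.vcf"),
                   contig_lengths = nchar(cohort$references))
  write_bed(cohort$blocks, file.path(dir, "blocks.bed"))
  write_bed(cohort$re_intervals, file.path(dir, "regulatory_elements.bed"))
  write.table(data.frame(sample = cohort$samples, label = sim$labels),
              file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$annotations$genes, file.path(dir, "causal_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(tf = rownames(sim$annotations$B), as.data.frame(sim$annotations$B)),
              file.path(dir, "binding_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  causal <- do.call(rbind, lapply(names(sim$annotations$causal_sets), function(g)
    data.frame(gene = g, site = cohort$sites$id[sim$annotations$causal_sets[[g]]])))
  write.table(causal, file.path(dir, "causal_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$cfg
  manifest <- list(
    package = "epiprs",
    config = cfg[setdiff(names(cfg), "geometry")],
    geometry = cfg$geometry[c("input_length", "n_bins", "bin_size")],
    config_hash = fnv1a_hash(cfg),
    coupled = cohort$coupled,
    n_cases = sum(sim$labels == 1L),
    alpha0 = sim$alpha0
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory back into pipeline inputs
#'
#' @param dir A directory written by [write_dataset()] (or assembled by
#'   hand with the same file names).
#' @return A list with `variants` (`phased_variants`), `references` (named
#'   character), `blocks`, `phenotypes` (data.frame `sample`, `label`) and
#'   `manifest` (list, or NULL).
#' @export
read_dataset <- function(dir) {
  refs <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  references <- setNames(as.character(refs), names(refs))
  variants <- filter_snvs(read_phased_vcf(file.path(dir, "genotypes.vcf")))
  blocks <- read_blocks_bed(file.path(dir, "blocks.bed"))
  phenotypes <- read.delim(file.path(dir, "phenotypes.tsv"), stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) jsonlite::read_json(manifest_path) else NULL
  list(variants = variants, references = references, blocks = blocks,
       phenotypes = phenotypes, manifest = manifest)
}
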