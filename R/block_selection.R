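#' Per-SNV allelic association scan
#'
#' For each site, tests the 2x2 allele-count by case-status table with a
#' 1-df chi-square (no continuity correction) and reports the two-sided
#' p-value. This is the built-in scan for synthetic cohorts; externally
#' supplied GWAS summary statistics bypass it.
#'
#' @param dosages Integer matrix (samples x sites) of alternate-allele
#'   dosages in {0, 1, 2}.
#' @param labels Binary vector (1 = case); both classes must be non-empty.
#' @param sites Optional data.frame with `id`, `chrom`, `pos` describing
#'   the columns of `dosages`.
#' @return A data.frame with `id`, `chrom`, `pos`, `chisq`, `p`.
#' @export
assoc_scan <- function(dosages, labels, sites = NULL) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop_epiprs("association scan needs both cases and controls")
  case <- labels == 1L
  n_case <- sum(case); n_ctrl <- sum(!case)
  alt_case <- colSums(dosages[case, , drop = FALSE])
  alt_ctrl <- colSums(dosages[!case, , drop = FALSE])
  a <- alt_case; b <- 2 * n_case - alt_case
  c_ <- alt_ctrl; d <- 2 * n_ctrl - alt_ctrl
  nn <- a + b + c_ + d
  c1 <- a + c_; c2 <- b + d
  if (any(c1 == 0 | c2 == 0))
    stop_epiprs("monomorphic site(s) in association scan: %s",
                paste(head(which(c1 == 0 | c2 == 0), 3), collapse = ", "))
  chisq <- nn * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * c1 * c2)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  if (is.null(sites))
    sites <- data.frame(id = colnames(dosages) %||% paste0("site_", seq_along(a)),
                        chrom = NA_character_, pos = NA_integer_)
  data.frame(id = sites$id, chrom = sites$chrom, pos = sites$pos,
             chisq = as.numeric(chisq), p = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Select LD blocks containing GWAS-significant SNVs
#'
#' A block is selected iff at least one SNV with `p < P0` falls inside its
#' interval (half-open containment of the 0-based position). SNVs outside
#' all blocks are counted in the `n_outside` attribute.
#'
#' @param stats Summary-statistic data.frame with `chrom`, `pos` (1-based)
#'   and `p` (as from [assoc_scan()] or [read_summary_stats()]).
#' @param blocks Block data.frame with `id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param P0 P-value threshold in (0, 1).
#' @return A data.frame report, one row per block: `id`, `chrom`, `start`,
#'   `end`, `n_sig`, `min_p`, `selected`; attribute `n_outside`.
#' @export
select_blocks <- function(stats, blocks, P0) {
  if (P0 <= 0 || P0 >= 1) stop_epiprs("P0 must lie strictly between 0 and 1")
  pos0 <- stats$pos - 1L
  block_of <- rep(NA_integer_, nrow(stats))
  for (b in seq_len(nrow(blocks))) {
    hit <- stats$chrom == blocks$chrom[b] &
      pos0 >= blocks$start[b] & pos0 < blocks$end[b]
    block_of[hit] <- b
  }
  n_outside <- sum(is.na(block_of))
  report <- blocks
  report$n_sig <- 0L
  report$min_p <- NA_real_
  sig <- stats$p < P0
  for (b in seq_len(nrow(blocks))) {
    inb <- which(block_of == b)
    if (length(inb)) report$min_p[b] <- min(stats$p[inb])
    report$n_sig[b] <- sum(sig[inb])
  }
  report$selected <- report$n_sig >= 1L
  attr(report, "n_outside") <- n_outside
  report
}

#' Read GWAS summary statistics from a TSV
#'
#' Expects columns `chrom`, `pos`, `id`, `p` (header required; extra
#' columns are carried through).
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with at least `chrom`, `pos`, `id`, `p`.
#' @export
read_summary_stats <- function(path) {
  stats <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "p")
  missing <- setdiff(need, names(stats))
  if (length(missing))
    stop_epiprs("summary statistics missing column(s): %s", paste(missing, collapse = ", "))
  if (any(stats$p <= 0 | stats$p > 1)) stop_epiprs("p-values must lie in (0, 1]")
  stats
}

#' Write a block-selection report as TSV
#' @param report Output of [select_blocks()].
#' @param path Output path.
#' @export
write_selection_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
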