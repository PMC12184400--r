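#' Model input window geometry
#'
#' Describes the fixed geometry of one sequence-to-feature model input: the
#' total input length, the number of central output bins and the bin size.
#' The central region (`n_bins * bin_size`) sits centered inside the input
#' interval; the flanks provide sequence context only. Defaults follow the
#' Enformer geometry (196,608 bp input, 896 central bins of 128 bp =
#' 114,688 bp central region).
#'
#' @param input_length Total input sequence length in bp.
#' @param n_bins Number of central, non-overlapping output bins.
#' @param bin_size Bin size in bp.
#' @return An object of class `window_config`.
#' @examples
#' cfg <- window_config()
#' cfg$central_length  # 896 * 128 = 114688
#' @export
window_config <- function(input_length = 196608L, n_bins = 896L, bin_size = 128L) {
  input_length <- as.integer(input_length)
  n_bins <- as.integer(n_bins)
  bin_size <- as.integer(bin_size)
  central <- n_bins * bin_size
  if (central > input_length)
    stop_epiprs("central region (%d bp) exceeds input length (%d bp)", central, input_length)
  if ((input_length - central) %% 2L != 0L)
    stop_epiprs("input_length - central_length must be even (got %d)", input_length - central)
  structure(
    list(input_length = input_length, n_bins = n_bins, bin_size = bin_size,
         central_length = central, margin = (input_length - central) %/% 2L),
    class = "window_config"
  )
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("window geometry: %d bp input, %d bins x %d bp (central %d bp, margin %d bp)\n",
              x$input_length, x$n_bins, x$bin_size, x$central_length, x$margin))
  invisible(x)
}

#' Tile an LD block with model input windows
#'
#' Lays non-overlapping central regions left-to-right from the block start
#' with stride equal to the central length, so the union of central bins
#' covers the whole block (the last window's central region may extend past
#' the block end). Input intervals extend `cfg$margin` bp to each side of
#' their central region; if an input interval would leave the contig, the
#' window is shifted inward and flagged.
#'
#' @param block A list or one-row data.frame with `id`, `chrom`, `start`,
#'   `end` (0-based, half-open).
#' @param cfg A [window_config()].
#' @param contig_length Optional contig length in bp, used to shift windows
#'   that would overhang the contig.
#' @return A data.frame of windows: `window`, `chrom`, `input_start`,
#'   `input_end`, `central_start`, `central_end`, `shifted`.
#' @export
tile_block <- function(block, cfg, contig_length = NULL) {
  start <- as.integer(block$start); end <- as.integer(block$end)
  len <- end - start
  if (len < 1L) stop_epiprs("block %s has non-positive length", block$id %||% "?")
  if (!is.null(contig_length) && contig_length < cfg$input_length)
    stop_epiprs("contig %s (%d bp) is shorter than the input length (%d bp)",
                block$chrom, contig_length, cfg$input_length)
  if (len < cfg$central_length) {
    # degenerate short block: one window centered on the block midpoint
    mid <- start + len %/% 2L
    cs <- mid - cfg$central_length %/% 2L
    centers <- cs
  } else {
    l <- ceiling(len / cfg$central_length)
    centers <- start + (seq_len(l) - 1L) * cfg$central_length
  }
  central_start <- as.integer(centers)
  input_start <- central_start - cfg$margin
  shifted <- rep(FALSE, length(input_start))
  # shift inward where the input interval leaves the contig
  low <- input_start < 0L
  input_start[low] <- 0L
  shifted <- shifted | low
  if (!is.null(contig_length)) {
    over <- input_start + cfg$input_length > contig_length
    input_start[over] <- as.integer(contig_length) - cfg$input_length
    shifted <- shifted | over
  }
  central_start <- input_start + cfg$margin
  data.frame(
    window = seq_along(input_start),
    chrom = rep(block$chrom, length(input_start)),
    input_start = input_start,
    input_end = input_start + cfg$input_length,
    central_start = central_start,
    central_end = central_start + cfg$central_length,
    shifted = shifted,
    stringsAsFactors = FALSE
  )
}

#' Bin coordinate grid of a window
#'
#' @param window One window (a list or one-row data.frame from
#'   [tile_block()]) with `input_start`.
#' @param cfg A [window_config()].
#' @return A data.frame with `bin` (1-based index), `start`, `end` (0-based
#'   half-open genomic coordinates) for all `cfg$n_bins` bins.
#' @export
bin_coordinates <- function(window, cfg) {
  cs <- as.integer(window$input_start) + cfg$margin
  starts <- cs + (seq_len(cfg$n_bins) - 1L) * cfg$bin_size
  data.frame(bin = seq_len(cfg$n_bins), start = starts, end = starts + cfg$bin_size)
}

#' Locate the bin containing a genomic position
#'
#' @inheritParams bin_coordinates
#' @param position 0-based genomic coordinate on the window's chromosome.
#' @return The 1-based bin index, or `NA_integer_` if the position falls
#'   outside the central region.
#' @export
locate_bin <- function(window, position, cfg) {
  cs <- as.integer(window$input_start) + cfg$margin
  off <- as.integer(position) - cs
  idx <- off %/% cfg$bin_size + 1L
  idx[off < 0L | idx > cfg$n_bins] <- NA_integer_
  idx
}

#' Read LD block definitions from a BED file
#'
#' BED is 0-based half-open; an optional 4th column supplies block ids
#' (defaults to `block_1`, `block_2`, ...). Blocks must be non-overlapping
#' within a chromosome.
#'
#' @param path Path to a BED file.
#' @return A data.frame with `id`, `chrom`, `start`, `end`.
#' @export
read_blocks_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, comment.char = "#", stringsAsFactors = FALSE)
  blocks <- data.frame(
    id = if (ncol(bed) >= 4) as.character(bed[[4]]) else paste0("block_", seq_len(nrow(bed))),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    stringsAsFactors = FALSE
  )
  for (chr in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == chr, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop_epiprs("overlapping blocks on %s", chr)
  }
  blocks
}

#' Write intervals as BED
#'
#' @param intervals A data.frame with `chrom`, `start`, `end` and optionally
#'   `id` (written as the 4th column).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, c("chrom", "start", "end")]
  if (!is.null(intervals$id)) cols$id <- intervals$id
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
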