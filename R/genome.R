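#' Genome model
#'
#' A minimal genome description: ordered chromosome names, lengths in base
#' pairs, and the fixed signal bin size. All signal tracks in a dataset share
#' one genome model and one bin grid.
#'
#' @param chrom_lengths Named integer/numeric vector of chromosome lengths
#'   (bp), names are chromosome identifiers. Order is preserved.
#' @param bin_size Signal bin width in bp (default 50, the analysis window
#'   convention used throughout the pipeline).
#' @return An object of class `genome_model`.
#' @examples
#' gm <- genome_model(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_model <- function(chrom_lengths, bin_size = 50L) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == "")) {
    stop_se("chrom_lengths must be a named vector", "se_validation_error")
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop_se("duplicate chromosome names", "se_validation_error")
  }
  if (any(chrom_lengths <= 0)) {
    stop_se("chromosome lengths must be > 0", "se_validation_error")
  }
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0) {
    stop_se("bin_size must be a positive integer", "se_validation_error")
  }
  structure(
    list(chroms = stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths)),
         bin_size = bin_size),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %.0f bp total, bin size %d bp\n",
              length(x$chroms), sum(x$chroms), x$bin_size))
  invisible(x)
}

#' Number of bins per chromosome
#' @param genome A `genome_model`.
#' @return Named integer vector.
#' @keywords internal
n_bins <- function(genome) {
  stats::setNames(as.integer(ceiling(genome$chroms / genome$bin_size)),
                  names(genome$chroms))
}

#' Construct a validated region table
#'
#' Regions are genomic intervals in the BED convention: 0-based start
#' (inclusive), end exclusive. This is the interval substrate used for
#' enhancers, super-enhancers, promoters and every other region set.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open.
#' @param id Optional region labels; autogenerated when `NULL`.
#' @param genome Optional `genome_model`; when given, coordinates are checked
#'   against chromosome bounds.
#' @return A `data.frame` with columns chrom, start, end, id.
#' @export
regions <- function(chrom, start, end, id = NULL, genome = NULL) {
  n <- length(start)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    stop_se("chrom, start, end must have equal length", "se_validation_error")
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (n > 0 && any(start < 0 | start >= end)) {
    stop_se("require 0 <= start < end for every region", "se_validation_error")
  }
  if (!is.null(genome)) {
    bad <- !(chrom %in% names(genome$chroms))
    if (any(bad)) {
      stop_se(sprintf("unknown chromosome(s): %s",
                      paste(unique(chrom[bad]), collapse = ", ")),
              "se_validation_error")
    }
    if (n > 0 && any(end > genome$chroms[chrom])) {
      stop_se("region end beyond chromosome length", "se_validation_error")
    }
  }
  if (is.null(id)) id <- if (n > 0) sprintf("region_%05d", seq_len(n)) else character(0)
  data.frame(chrom = as.character(chrom), start = start, end = end,
             id = as.character(id), stringsAsFactors = FALSE)
}

#' @keywords internal
region_width <- function(reg) reg$end - reg$start

#' Sort a region table by chromosome then start
#' @param reg Region data.frame.
#' @return The sorted data.frame.
#' @export
sort_regions <- function(reg) {
  reg[order(reg$chrom, reg$start, reg$end), , drop = FALSE]
}

#' @keywords internal
as_granges <- function(reg) {
  GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(reg$start + 1, reg$end))
}

#' @keywords internal
granges_to_regions <- function(gr, id = NULL) {
  regions(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1,
          GenomicRanges::end(gr),
          id = id)
}

#' Merge overlapping intervals (>= 1 bp overlap)
#'
#' Intervals overlapping by at least one base are merged transitively into
#' their union span; abutting intervals (zero overlap) are kept separate.
#'
#' @param reg Region data.frame.
#' @param id_prefix Prefix for merged region ids.
#' @return Merged, sorted region data.frame.
#' @export
merge_regions <- function(reg, id_prefix = "merged") {
  if (nrow(reg) == 0) return(reg)
  gr <- GenomicRanges::reduce(as_granges(reg), min.gapwidth = 0L)
  out <- granges_to_regions(gr)
  out$id <- sprintf("%s_%05d", id_prefix, seq_len(nrow(out)))
  sort_regions(out)
}

#' Internal condition helper
#' @keywords internal
stop_se <- function(msg, class = "se_error", call. = FALSE) {
  stop(structure(class = c(class, "se_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1) else NULL)))
}
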