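#' Stitch predicted enhancers into super-enhancer candidates
#'
#' Enhancers within `gap` bp of each other (inter-interval gap, transitively
#' chained) are stitched into one region spanning from the first start to the
#' last end. A lone enhancer is its own stitched region.
#'
#' @param enhancers Sorted, non-overlapping region data.frame (one sample).
#' @param gap Maximum stitching gap in bp (default 12,500).
#' @return List with `regions` (stitched spans, plus `n_constituents` and
#'   `constituent_bp`) and `membership` (stitched-region index per input row).
#' @export
stitch <- function(enhancers, gap = 12500) {
  n <- nrow(enhancers)
  if (n == 0) {
    out <- regions(character(0), numeric(0), numeric(0))
    out$n_constituents <- integer(0); out$constituent_bp <- numeric(0)
    return(list(regions = out, membership = integer(0)))
  }
  o <- order(enhancers$chrom, enhancers$start)
  if (!identical(o, seq_len(n))) {
    stop_se("enhancers must be sorted by chrom, start", "se_validation_error")
  }
  same_chrom <- c(FALSE, enhancers$chrom[-1] == enhancers$chrom[-n])
  if (n > 1 && any(same_chrom & c(Inf, enhancers$start[-1]) < c(Inf, enhancers$end[-n]))) {
    stop_se("enhancers must be non-overlapping within a sample", "se_validation_error")
  }
  gap_prev <- c(Inf, enhancers$start[-1] - enhancers$end[-n])
  new_chain <- !(same_chrom & gap_prev <= gap)
  membership <- cumsum(new_chain)
  sp_start <- tapply(enhancers$start, membership, min)
  sp_end <- tapply(enhancers$end, membership, max)
  sp_chrom <- tapply(enhancers$chrom, membership, `[`, 1)
  out <- regions(as.character(sp_chrom), as.numeric(sp_start), as.numeric(sp_end),
                 id = sprintf("stitch_%05d", seq_along(sp_start)))
  out$n_constituents <- as.integer(table(membership))
  out$constituent_bp <- as.numeric(tapply(enhancers$end - enhancers$start,
                                          membership, sum))
  list(regions = out, membership = as.integer(membership))
}

#' Hockey-stick (ranked signal) super-enhancer cutoff
#'
#' Sorts total signals ascending, rescales rank and signal to the unit
#' square, and places the cutoff at the point maximizing `x - y` -- the
#' slope-1 tangent point of the convex "hockey stick". Regions with signal
#' strictly above the cutoff signal are super-enhancers. Ties in the argmax
#' break to the largest index (fewer super-enhancers, conservative).
#'
#' @param signals Non-negative numeric vector, one total signal per stitched
#'   region (length >= 3).
#' @return List of class `cutoff_result`: `order` (ascending permutation),
#'   `sorted_signals`, `scaled_x`, `scaled_y`, `cutoff_index` (into the
#'   sorted vector), `cutoff_signal`, and `is_super` in input order.
#' @export
se_cutoff <- function(signals) {
  n <- length(signals)
  if (n < 3) stop_se("need >= 3 stitched regions", "se_validation_error")
  if (any(signals < 0)) stop_se("signals must be >= 0", "se_validation_error")
  o <- order(signals)
  s <- signals[o]
  if (s[1] == s[n]) {
    warning("all stitched signals equal; no super-enhancers called")
    return(structure(list(order = o, sorted_signals = s,
                          scaled_x = (seq_len(n) - 1) / (n - 1),
                          scaled_y = rep(0, n),
                          cutoff_index = n, cutoff_signal = s[n],
                          is_super = rep(FALSE, n)),
                     class = "cutoff_result"))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  d <- x - y
  cutoff_index <- max(which(d == max(d))) # tie to largest index
  cutoff_signal <- s[cutoff_index]
  structure(list(order = o, sorted_signals = s, scaled_x = x, scaled_y = y,
                 cutoff_index = cutoff_index, cutoff_signal = cutoff_signal,
                 is_super = signals > cutoff_signal),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff_result: %d regions, cutoff signal %.4g, %d super-enhancer(s)\n",
              length(x$sorted_signals), x$cutoff_signal, sum(x$is_super)))
  invisible(x)
}

#' Super-enhancer ranking signal
#'
#' Input-corrected H3K27ac signal summed over the constituent intervals of
#' each stitched region. The default (`normalize = "total"`) is the
#' ROSE-style total corrected signal (library-normalized corrected reads
#' summed over constituents, in RPM x bp units); `"extent"` divides by the
#' stitched span instead, i.e. RPKM on the extent. Total signal is the
#' default because extent density systematically ranks a single strong
#' constituent above genuine multi-constituent clusters.
#'
#' @param stitched Result of [stitch()].
#' @param enhancers The constituent region data.frame passed to [stitch()].
#' @param chip,input `signal_track`s for the sample.
#' @param genome A `genome_model`.
#' @param normalize `"total"` (default) or `"extent"`.
#' @return Numeric vector, one signal per stitched region.
#' @export
stitched_signal <- function(stitched, enhancers, chip, input, genome,
                            normalize = c("total", "extent")) {
  normalize <- match.arg(normalize)
  cr <- corrected_rpkm(chip, input, enhancers, genome)
  w <- region_width(enhancers)
  reads_equiv <- cr * w # corrected reads x 1e9 / library
  tot <- as.numeric(tapply(reads_equiv, stitched$membership, sum))
  if (normalize == "extent") tot / region_width(stitched$regions) else tot
}

#' Merge per-line super-enhancers into a non-redundant catalog
#'
#' Identical contract to [merge_catalog()] (>= 1 bp overlap, transitive).
#'
#' @param se_by_line Named list of per-line super-enhancer region tables.
#' @return Merged catalog with `present_in` / `n_samples`.
#' @export
merge_se_across_lines <- function(se_by_line) {
  merge_catalog(se_by_line, id_prefix = "SE")
}

#' Typical-enhancer catalog
#'
#' Merged predicted enhancers whose territory does not overlap the merged
#' super-enhancer catalog (>= 1 bp overlap removes a region).
#'
#' @param enhancer_catalog,se_catalog Merged region tables.
#' @return Region data.frame of typical enhancers.
#' @export
typical_enhancers <- function(enhancer_catalog, se_catalog) {
  if (nrow(enhancer_catalog) == 0) return(enhancer_catalog)
  if (nrow(se_catalog) == 0) return(enhancer_catalog)
  hits <- GenomicRanges::findOverlaps(as_granges(enhancer_catalog),
                                      as_granges(se_catalog), minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- enhancer_catalog[setdiff(seq_len(nrow(enhancer_catalog)), drop), ,
                          drop = FALSE]
  rownames(out) <- NULL
  out
}
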