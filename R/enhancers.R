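#' Candidate enriched-region calling by threshold runs
#'
#' A deliberately simple caller: maximal runs of contiguous bins whose
#' corrected signal strictly exceeds a threshold, kept when at least
#' `min_width` bp wide. Stands in for an external peak caller; externally
#' called peaks can be supplied as BED instead.
#'
#' @param signal_bins Named list of per-chromosome per-bin corrected signal
#'   vectors (see [corrected_bin_signal()]).
#' @param genome A `genome_model`.
#' @param threshold Signal threshold (e.g. a [build_background()] q99).
#' @param min_width Minimum region width in bp (default 200).
#' @return Sorted, non-overlapping region data.frame.
#' @export
call_candidate_regions <- function(signal_bins, genome, threshold,
                                   min_width = 200) {
  bs <- genome$bin_size
  parts <- list()
  for (chrom in names(signal_bins)) {
    above <- signal_bins[[chrom]] > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths # 0-based bin index of run start
    keep <- r$values & (r$lengths * bs >= min_width)
    if (any(keep)) {
      parts[[chrom]] <- data.frame(
        chrom = chrom,
        start = starts[keep] * bs,
        end = pmin(ends[keep] * bs, genome$chroms[[chrom]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(parts) == 0) return(regions(character(0), numeric(0), numeric(0)))
  df <- do.call(rbind, parts)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  regions(df$chrom, df$start, df$end,
          id = sprintf("cand_%05d", seq_len(nrow(df))), genome = genome)
}

#' Distance from regions to the nearest TSS
#'
#' Distance is the minimum over covered bases of `|base - tss_pos|`: zero
#' when a TSS falls inside the region, else the gap to the closest region
#' end base. Strand is ignored.
#'
#' @param reg Region data.frame.
#' @param tss TSS table with columns `chrom`, `pos` (0-based).
#' @return Numeric vector of distances (Inf when the chromosome has no TSS).
#' @export
distance_to_nearest_tss <- function(reg, tss) {
  out <- rep(Inf, nrow(reg))
  for (chrom in unique(reg$chrom)) {
    pos <- sort(tss$pos[tss$chrom == chrom])
    idx <- which(reg$chrom == chrom)
    if (length(pos) == 0) next
    s <- reg$start[idx]; e <- reg$end[idx] - 1 # last covered base
    # nearest TSS to the closed base interval [s, e]
    a <- findInterval(s - 0.5, pos)    # number of TSS strictly left of s
    b <- findInterval(e, pos)          # number of TSS <= e
    inside <- b > a
    d_left <- ifelse(a >= 1, s - pos[pmax(a, 1)], Inf)
    d_right <- ifelse(b < length(pos), pos[pmin(b + 1, length(pos))] - e, Inf)
    d <- pmin(d_left, d_right)
    d[inside] <- 0
    out[idx] <- d
  }
  out
}

#' Filter candidates to predicted enhancers
#'
#' Keeps candidate regions that are (a) distal -- at least `min_tss_dist` bp
#' from every annotated TSS -- and (b) enhancer-like by the aggregate
#' H3K4me3/H3K4me1 log2 ratio, `log2((me3 + c)/(me1 + c)) <= max_ratio`.
#' Candidates with high ratios are promoter-like mistaken predictions.
#'
#' @param candidates Region data.frame.
#' @param tss TSS table (`gene_id`, `chrom`, `pos`, `strand`).
#' @param k4me3,k4me1 Aggregate `signal_track`s (pooled across samples).
#' @param genome A `genome_model`.
#' @param min_tss_dist Distal cutoff in bp (default 2500).
#' @param max_ratio Exclusion threshold on the log2 ratio (default 2.4).
#' @param pseudocount Pseudocount `c` on both marks (default 0.1).
#' @return The candidate table plus `distance_to_tss`, `k4_log_ratio`,
#'   `is_distal`, restricted to retained rows.
#' @export
filter_to_predicted_enhancers <- function(candidates, tss, k4me3, k4me1,
                                          genome, min_tss_dist = 2500,
                                          max_ratio = 2.4, pseudocount = 0.1) {
  if (is.null(tss) || nrow(tss) == 0) {
    stop_se("empty TSS annotation", "se_validation_error")
  }
  out <- candidates
  out$distance_to_tss <- distance_to_nearest_tss(candidates, tss)
  out$is_distal <- out$distance_to_tss >= min_tss_dist
  if (nrow(candidates) > 0) {
    me3 <- compute_rpkm(k4me3, candidates, genome)
    me1 <- compute_rpkm(k4me1, candidates, genome)
    out$k4_log_ratio <- log2((me3 + pseudocount) / (me1 + pseudocount))
  } else {
    out$k4_log_ratio <- numeric(0)
  }
  out[out$is_distal & out$k4_log_ratio <= max_ratio, , drop = FALSE]
}

#' Merge per-sample calls into a unified catalog
#'
#' Regions overlapping by at least one base across samples are merged
#' transitively; each merged region records the contributing samples.
#'
#' @param calls_by_sample Named list of region data.frames.
#' @param id_prefix Prefix for merged ids.
#' @return Merged region data.frame with `present_in` (comma-joined sample
#'   names) and `n_samples`.
#' @export
merge_catalog <- function(calls_by_sample, id_prefix = "cat") {
  all_reg <- do.call(rbind, lapply(names(calls_by_sample), function(s) {
    r <- calls_by_sample[[s]][, c("chrom", "start", "end")]
    if (nrow(r) > 0) r$sample <- s
    r
  }))
  if (is.null(all_reg) || nrow(all_reg) == 0) {
    out <- regions(character(0), numeric(0), numeric(0))
    out$present_in <- character(0); out$n_samples <- integer(0)
    return(out)
  }
  merged <- merge_regions(regions(all_reg$chrom, all_reg$start, all_reg$end),
                          id_prefix = id_prefix)
  hits <- GenomicRanges::findOverlaps(as_granges(merged),
                                      as_granges(all_reg), minoverlap = 1L)
  pres <- tapply(all_reg$sample[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits),
                 function(s) sort(unique(s)), simplify = FALSE)
  merged$present_in <- vapply(seq_len(nrow(merged)), function(i) {
    p <- pres[[as.character(i)]]
    if (is.null(p)) "" else paste(p, collapse = ",")
  }, "")
  merged$n_samples <- lengths(strsplit(merged$present_in, ","))
  merged
}

#' Rank-product recurrence across lines
#'
#' Within each line, regions are ranked by descending signal (rank 1 =
#' strongest, ties get average ranks); the per-region rank product is the
#' product of its ranks over lines. Significance comes from a permutation
#' null: each line's rank vector is independently reshuffled `n_perm` times
#' and, per region, the empirical p-value is
#' `(1 + #(null RP <= observed RP)) / (1 + n_perm)`.
#'
#' @param mat Numeric matrix, regions x lines (rownames = region ids).
#' @param n_perm Number of permutations (default 10,000; minimum 100).
#' @param seed Optional seed.
#' @param present Optional logical matrix of per-line presence; default
#'   `mat > 0`. A region is recurrent when present in >= 2 lines.
#' @return data.frame: id, rank_product, p_empirical, n_present,
#'   is_recurrent, plus per-line rank columns.
#' @export
rank_product_recurrence <- function(mat, n_perm = 10000L, seed = NULL,
                                    present = NULL) {
  if (is.null(dim(mat)) || ncol(mat) < 2) {
    stop_se("need a regions x lines matrix with >= 2 lines", "se_validation_error")
  }
  if (n_perm < 100) stop_se("n_perm < 100", "se_validation_error")
  n <- nrow(mat); k <- ncol(mat)
  ranks <- apply(mat, 2, function(x) rank(-x, ties.method = "average"))
  ranks <- matrix(ranks, nrow = n)
  log_obs <- rowSums(log(ranks))
  count <- with_seed_(seed, {
    cnt <- integer(n)
    for (b in seq_len(n_perm)) {
      log_null <- numeric(n)
      for (j in seq_len(k)) {
        log_null <- log_null + log(ranks[sample.int(n), j])
      }
      cnt <- cnt + (log_null <= log_obs + 1e-12)
    }
    cnt
  })
  if (is.null(present)) present <- mat > 0
  out <- data.frame(
    id = if (is.null(rownames(mat))) sprintf("region_%05d", seq_len(n)) else rownames(mat),
    rank_product = exp(log_obs),
    p_empirical = (1 + count) / (1 + n_perm),
    n_present = rowSums(present),
    stringsAsFactors = FALSE)
  out$is_recurrent <- out$n_present >= 2
  rk <- as.data.frame(ranks)
  names(rk) <- paste0("rank_", if (is.null(colnames(mat))) seq_len(k) else colnames(mat))
  cbind(out, rk)
}
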