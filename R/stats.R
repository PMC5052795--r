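# Downstream integration statistics: SNP enrichment, TF occupancy,
# meta-profiles, knockdown depletion, permutation tests, conservation.

# Point-in-region membership for 0-based positions against a sorted,
# non-overlapping region set.
points_in_regions <- function(chrom, pos, reg) {
  inside <- logical(length(pos))
  for (cm in unique(chrom)) {
    r <- reg[reg$chrom == cm, , drop = FALSE]
    idx <- which(chrom == cm)
    if (nrow(r) == 0) next
    o <- order(r$start)
    s <- r$start[o]; e <- r$end[o]
    k <- findInterval(pos[idx], s)
    inside[idx] <- k >= 1 & pos[idx] < e[pmax(k, 1)]
  }
  inside
}

#' GWAS SNP enrichment in a region set
#'
#' Per trait, counts trait SNPs inside/outside the region set (nGWAS,
#' nGWAS'), the same for a background SNP catalog (nBackground,
#' nBackground'), and reports the enrichment ratio
#' `(nGWAS/nGWAS') / (nBackground/nBackground')` with a chi-square test on
#' the 2x2 table (1 df, no continuity correction by default). Traits with
#' fewer than `min_trait_in` SNPs inside the region set are excluded.
#'
#' @param trait_snps data.frame `chrom`, `pos` (0-based), `id`, `trait`.
#' @param background_snps data.frame `chrom`, `pos`, `id`.
#' @param se_set Region data.frame (merged / non-overlapping).
#' @param min_trait_in Minimum trait SNPs inside the set (default 10).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return data.frame per retained trait: trait, n_gwas_in, n_gwas_out,
#'   n_background_in, n_background_out, enrichment_ratio, chi2_p.
#' @export
snp_enrichment <- function(trait_snps, background_snps, se_set,
                           min_trait_in = 10L, correct = FALSE) {
  if (is.null(background_snps) || nrow(background_snps) == 0) {
    stop_se("empty background SNP set", "se_validation_error")
  }
  bg_in <- sum(points_in_regions(background_snps$chrom, background_snps$pos, se_set))
  bg_out <- nrow(background_snps) - bg_in
  traits <- unique(trait_snps$trait)
  rows <- lapply(traits, function(tr) {
    snp <- trait_snps[trait_snps$trait == tr, , drop = FALSE]
    n_in <- sum(points_in_regions(snp$chrom, snp$pos, se_set))
    n_out <- nrow(snp) - n_in
    if (n_in < min_trait_in) {
      message(sprintf("trait '%s' excluded (%d < %d SNPs in region set)",
                      tr, n_in, min_trait_in))
      return(NULL)
    }
    ratio <- if (n_out == 0 || bg_in == 0 || bg_out == 0) NA_real_
             else (n_in / n_out) / (bg_in / bg_out)
    tab <- matrix(c(n_in, n_out, bg_in, bg_out), 2, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
         else suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
    data.frame(trait = tr, n_gwas_in = n_in, n_gwas_out = n_out,
               n_background_in = bg_in, n_background_out = bg_out,
               enrichment_ratio = ratio, chi2_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trait = character(0), n_gwas_in = integer(0),
                      n_gwas_out = integer(0), n_background_in = integer(0),
                      n_background_out = integer(0),
                      enrichment_ratio = numeric(0), chi2_p = numeric(0))
  }
  out
}

#' TF binding-site density over a region set
#'
#' Counts sites whose overlap with the (merged, non-overlapping) region set
#' is at least `min_overlap_frac` of the site length -- single-base summits
#' reduce to membership -- and divides by the total region size in Mbp.
#'
#' @param sites Region data.frame of binding sites or summits.
#' @param region_set Merged region data.frame.
#' @param min_overlap_frac Required overlap fraction (default 0.6).
#' @return List: `n_sites`, `density_per_mbp`.
#' @export
tf_density <- function(sites, region_set, min_overlap_frac = 0.6) {
  total_bp <- sum(region_width(region_set))
  if (total_bp <= 0) stop_se("zero-length region set", "se_validation_error")
  if (nrow(sites) == 0) return(list(n_sites = 0L, density_per_mbp = 0))
  hits <- GenomicRanges::findOverlaps(as_granges(sites), as_granges(region_set))
  ovl <- numeric(nrow(sites))
  if (length(hits) > 0) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    piece <- pmin(sites$end[q], region_set$end[s]) -
      pmax(sites$start[q], region_set$start[s])
    agg <- tapply(piece, q, sum)
    ovl[as.integer(names(agg))] <- agg
  }
  n <- sum(ovl >= min_overlap_frac * region_width(sites))
  list(n_sites = as.integer(n), density_per_mbp = n / (total_bp / 1e6))
}

#' Summit co-occupancy within a window
#'
#' Fraction of summits in `summits_a` that have at least one summit of
#' `summits_b` within `window` bp (absolute midpoint distance, same
#' chromosome).
#'
#' @param summits_a,summits_b Region data.frames of summits (midpoints are
#'   used for width > 1).
#' @param window Distance threshold in bp (default 500).
#' @return Fraction in `[0, 1]`.
#' @export
cooccupancy <- function(summits_a, summits_b, window = 500) {
  if (nrow(summits_a) == 0) stop_se("empty summits_a", "se_validation_error")
  if (nrow(summits_b) == 0) return(0)
  mid <- function(r) floor((r$start + r$end) / 2)
  ma <- mid(summits_a); mb <- mid(summits_b)
  hit <- logical(nrow(summits_a))
  for (cm in unique(summits_a$chrom)) {
    ia <- which(summits_a$chrom == cm)
    pb <- sort(mb[summits_b$chrom == cm])
    if (length(pb) == 0) next
    k <- findInterval(ma[ia], pb)
    d_left <- ifelse(k >= 1, ma[ia] - pb[pmax(k, 1)], Inf)
    d_right <- ifelse(k < length(pb), pb[pmin(k + 1, length(pb))] - ma[ia], Inf)
    hit[ia] <- pmin(d_left, d_right) <= window
  }
  mean(hit)
}

#' Binned meta-profile over regions
#'
#' Divides each region into `n_bins` equal-width slices (fractional overlap
#' with genome bins prorated) and reports per-slice signal in RPKM. Row sums
#' weighted by slice length conserve each region's total signal.
#'
#' @param track A `signal_track`.
#' @param reg Region data.frame (each region at least `n_bins` bp long).
#' @param genome A `genome_model`.
#' @param n_bins Number of slices (default 200).
#' @return Numeric matrix regions x n_bins (RPKM).
#' @export
binned_profile <- function(track, reg, genome, n_bins = 200L) {
  if (any(region_width(reg) < n_bins)) {
    stop_se(sprintf("region shorter than n_bins = %d bp", n_bins),
            "se_validation_error")
  }
  out <- matrix(NA_real_, nrow(reg), n_bins, dimnames = list(reg$id, NULL))
  for (i in seq_len(nrow(reg))) {
    edges <- reg$start[i] + (reg$end[i] - reg$start[i]) * (0:n_bins) / n_bins
    sub <- regions(rep(reg$chrom[i], n_bins), edges[-(n_bins + 1)], edges[-1])
    out[i, ] <- compute_rpkm(track, sub, genome)
  }
  out
}

#' Knockdown H3K27ac depletion calls
#'
#' Tiles the analysis regions into `subregion_width` bp windows, computes
#' per-window RPKM for each wild-type replicate and the knockdown track, and
#' calls each window against the empirical background variation of WT-vs-WT
#' differences: *depleted* when `mean(WT) - KD` exceeds the background 99th
#' percentile, *gained* when below the 1st percentile, else *unchanged*.
#'
#' Because the call statistic averages `m` WT replicates while the background
#' is built from single-replicate differences, the pooled background is
#' rescaled by `sqrt((1 + 1/m)/2)` by default so that its quantiles match the
#' sampling variation of `mean(WT) - KD` under no knockdown effect; set
#' `scale_background = FALSE` for the raw pairwise quantiles.
#'
#' @param wt_tracks List of >= 2 wild-type `signal_track`s.
#' @param kd_track Knockdown `signal_track`.
#' @param reg Analysis region data.frame.
#' @param genome A `genome_model`.
#' @param subregion_width Tiling window in bp (default 1000).
#' @param scale_background See above (default TRUE).
#' @param region_class Optional per-region labels (e.g. "super" /
#'   "typical") propagated to subregions for the class comparison.
#' @return List of class `depletion_calls`: `subregions` (with `diff`,
#'   `state`, optional `class`), `q1`, `q99`, `background`, and `wilcox_p`
#'   (one-sided test that "super" depletion magnitudes exceed "typical")
#'   when `region_class` is given.
#' @export
knockdown_depletion <- function(wt_tracks, kd_track, reg, genome,
                                subregion_width = 1000, scale_background = TRUE,
                                region_class = NULL) {
  m <- length(wt_tracks)
  if (m < 2) stop_se("need >= 2 wild-type replicates", "se_validation_error")
  sub <- tile_regions(reg, subregion_width, region_class)
  wt <- sapply(wt_tracks, compute_rpkm, reg = sub, genome = genome)
  wt <- matrix(wt, nrow = nrow(sub))
  kd <- compute_rpkm(kd_track, sub, genome)
  bg <- numeric(0)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    bg <- c(bg, wt[, i] - wt[, j], wt[, j] - wt[, i])
  }
  if (scale_background) bg <- bg * sqrt((1 + 1 / m) / 2)
  q1 <- unname(stats::quantile(bg, 0.01, type = 1))
  q99 <- unname(stats::quantile(bg, 0.99, type = 1))
  diff <- rowMeans(wt) - kd
  state <- rep("unchanged", nrow(sub))
  state[diff > q99] <- "depleted"
  state[diff < q1] <- "gained"
  sub$diff <- diff
  sub$state <- state
  wilcox_p <- NA_real_
  if (!is.null(region_class)) {
    sup <- diff[sub$class == "super"]; typ <- diff[sub$class == "typical"]
    if (length(sup) >= 2 && length(typ) >= 2) {
      wilcox_p <- stats::wilcox.test(sup, typ, alternative = "greater",
                                     exact = FALSE)$p.value
    }
  }
  structure(list(subregions = sub, q1 = q1, q99 = q99, background = bg,
                 wilcox_p = wilcox_p),
            class = "depletion_calls")
}

# Tile regions into fixed windows; trailing partial windows are dropped.
tile_regions <- function(reg, width, region_class = NULL) {
  parts <- lapply(seq_len(nrow(reg)), function(i) {
    n <- floor((reg$end[i] - reg$start[i]) / width)
    if (n < 1) return(NULL)
    st <- reg$start[i] + (0:(n - 1)) * width
    d <- data.frame(chrom = reg$chrom[i], start = st, end = st + width,
                    region_id = reg$id[i], stringsAsFactors = FALSE)
    if (!is.null(region_class)) d$class <- region_class[i]
    d
  })
  df <- do.call(rbind, parts)
  if (is.null(df)) stop_se("no subregion fits the tiling width", "se_validation_error")
  out <- regions(df$chrom, df$start, df$end,
                 id = sprintf("sub_%06d", seq_len(nrow(df))))
  out$region_id <- df$region_id
  if (!is.null(region_class)) out$class <- df$class
  out
}

#' Target-downregulation permutation test
#'
#' Observed statistic: number of downregulated genes among those linked to
#' depleted super-enhancers. Null: gene assignments are redrawn uniformly
#' (with replacement) from the expression universe `n_perm` times; the
#' empirical p-value is `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param linked_genes Character vector of linked gene ids.
#' @param down_flags Named logical vector over the gene universe (TRUE =
#'   downregulated).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Optional seed.
#' @return List: observed, n_links, fraction_down, p_empirical.
#' @export
target_downregulation_permutation <- function(linked_genes, down_flags,
                                              n_perm = 10000L, seed = NULL) {
  k <- length(linked_genes)
  if (k == 0) stop_se("empty link set", "se_validation_error")
  if (!all(linked_genes %in% names(down_flags))) {
    stop_se("linked genes missing from the expression universe",
            "se_validation_error")
  }
  observed <- sum(down_flags[linked_genes])
  null_counts <- with_seed_(seed, {
    draws <- matrix(sample(unname(down_flags), k * n_perm, replace = TRUE),
                    nrow = k)
    colSums(draws)
  })
  list(observed = observed, n_links = k, fraction_down = observed / k,
       p_empirical = (1 + sum(null_counts >= observed)) / (1 + n_perm))
}

#' Conservation score of an enhancer
#'
#' Maximum of a per-bin conservation score track within 500 bp of the region
#' midpoint. Bins without coverage are NA; NA is returned when the whole
#' window lacks coverage.
#'
#' @param reg Region data.frame.
#' @param score_bins Named list of per-chromosome score vectors on the
#'   genome bin grid (NA = no coverage).
#' @param genome A `genome_model`.
#' @param window Half-window in bp (default 500).
#' @return Numeric vector of max scores.
#' @export
conservation_max <- function(reg, score_bins, genome, window = 500) {
  bs <- genome$bin_size
  vapply(seq_len(nrow(reg)), function(i) {
    if (!reg$chrom[i] %in% names(score_bins)) {
      stop_se(sprintf("no conservation track for %s", reg$chrom[i]),
              "se_validation_error")
    }
    v <- score_bins[[reg$chrom[i]]]
    midpoint <- floor((reg$start[i] + reg$end[i]) / 2)
    lo <- max(midpoint - window, 0)
    hi <- min(midpoint + window, genome$chroms[[reg$chrom[i]]])
    b0 <- lo %/% bs + 1
    b1 <- min(ceiling(hi / bs), length(v))
    w <- v[b0:b1]
    if (all(is.na(w))) NA_real_ else max(w, na.rm = TRUE)
  }, 0)
}
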