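#' Active promoter detection
#'
#' A promoter is the `flank`-bp window either side of the TSS (clipped to
#' chromosome bounds). A TSS is active when its input-corrected H3K27ac RPKM
#' strictly exceeds the random-region background 99th percentile in at least
#' one sample of the analysis set (`rule = "any"`, the default) or in a
#' majority of samples (`rule = "majority"`).
#'
#' @param tss TSS table (`gene_id`, `chrom`, `pos`, `strand`).
#' @param chip_tracks List of H3K27ac `signal_track`s.
#' @param input_tracks Matched list of input tracks (same order; entries may
#'   be `NULL`).
#' @param genome A `genome_model`.
#' @param background A `background_model` built for `2 * flank` bp windows.
#' @param flank Promoter flank in bp (default 500).
#' @param rule "any" or "majority".
#' @return The TSS table plus logical column `active` and
#'   `promoter_rpkm` (max corrected RPKM across samples).
#' @export
active_promoters <- function(tss, chip_tracks, input_tracks, genome,
                             background, flank = 500, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  prom <- regions(tss$chrom,
                  pmax(tss$pos - flank, 0),
                  pmin(tss$pos + flank, genome$chroms[tss$chrom]),
                  id = tss$gene_id, genome = genome)
  vals <- sapply(seq_along(chip_tracks), function(k) {
    corrected_rpkm(chip_tracks[[k]], input_tracks[[k]], prom, genome)
  })
  vals <- matrix(vals, nrow = nrow(tss))
  hits <- vals > background$threshold_p99
  n_hit <- rowSums(hits)
  out <- tss
  out$promoter_rpkm <- apply(vals, 1, max)
  out$active <- if (rule == "any") n_hit >= 1 else n_hit > length(chip_tracks) / 2
  out
}

#' Assign super-enhancers to their nearest active TSS
#'
#' The assignment measures from the region centre, `floor((start + end)/2)`,
#' to each active TSS position on the same chromosome and links the closest
#' one; equidistant ties break to the smaller coordinate. Also flags whether
#' the linked gene is the closest gene overall (ignoring activity).
#'
#' @param se_regions Region data.frame with `id`.
#' @param tss TSS table with logical `active` column (see
#'   [active_promoters()]).
#' @return data.frame: se_id, gene_id, tss_pos, distance,
#'   is_closest_gene_overall. Unassigned regions (no active TSS on the
#'   chromosome) carry NA and are reported.
#' @export
assign_nearest_active <- function(se_regions, tss) {
  stopifnot(!is.null(tss$active))
  center <- floor((se_regions$start + se_regions$end) / 2)
  nearest <- function(center, cand) {
    # candidate table sorted by pos; returns index of nearest, tie -> smaller pos
    if (nrow(cand) == 0) return(NA_integer_)
    d <- abs(cand$pos - center)
    which(d == min(d))[1] # cand sorted by pos, first hit is smaller coordinate
  }
  out <- data.frame(se_id = se_regions$id, gene_id = NA_character_,
                    tss_pos = NA_real_, distance = NA_real_,
                    is_closest_gene_overall = NA, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(se_regions))) {
    on_chrom <- tss[tss$chrom == se_regions$chrom[i], , drop = FALSE]
    on_chrom <- on_chrom[order(on_chrom$pos), , drop = FALSE]
    act <- on_chrom[on_chrom$active, , drop = FALSE]
    j <- nearest(center[i], act)
    if (is.na(j)) next
    out$gene_id[i] <- act$gene_id[j]
    out$tss_pos[i] <- act$pos[j]
    out$distance[i] <- abs(act$pos[j] - center[i])
    k <- nearest(center[i], on_chrom)
    out$is_closest_gene_overall[i] <- identical(on_chrom$gene_id[k], act$gene_id[j])
  }
  if (anyNA(out$gene_id)) {
    message(sprintf("%d super-enhancer(s) unassigned (no active TSS on chromosome)",
                    sum(is.na(out$gene_id))))
  }
  out
}

#' One-sided gene-set enrichment (Fisher's exact test)
#'
#' Tests over-representation of `gene_set` among `genes` within `universe`
#' with a one-sided (greater) Fisher's exact test on the 2x2 table. Used for
#' the top-500 oncogene list, cancer-hallmark sets, and any user set.
#'
#' @param genes Character vector of query genes (e.g. super-enhancer-linked).
#' @param gene_set Character vector, the set being tested.
#' @param universe Character vector containing both.
#' @return List of class `enrichment_result`: n_overlap, odds_ratio (sample
#'   odds ratio), p_value, table.
#' @export
geneset_enrichment <- function(genes, gene_set, universe) {
  if (length(universe) == 0) stop_se("empty universe", "se_validation_error")
  genes <- unique(genes); gene_set <- unique(gene_set); universe <- unique(universe)
  if (!all(genes %in% universe) || !all(gene_set %in% universe)) {
    stop_se("universe must contain the query genes and the gene set",
            "se_validation_error")
  }
  a <- length(intersect(genes, gene_set))
  b <- length(setdiff(genes, gene_set))
  cc <- length(setdiff(gene_set, genes))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(c("query", "not_query"), c("in_set", "not_in_set")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- if (b * cc == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else a * d / (b * cc)
  structure(list(n_overlap = a, odds_ratio = or, p_value = p, table = tab),
            class = "enrichment_result")
}

#' @rdname geneset_enrichment
#' @param oncogenes Character vector (e.g. a top-500 oncogene list).
#' @export
oncogene_enrichment <- function(genes, oncogenes, universe) {
  geneset_enrichment(genes, oncogenes, universe)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: overlap %d, OR %.3g, one-sided Fisher p = %.3g\n",
              x$n_overlap, x$odds_ratio, x$p_value))
  invisible(x)
}
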