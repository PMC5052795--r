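#' Pipeline configuration defaults
#'
#' Every threshold defaults to its printed convention: 2.5 kb distal filter,
#' 2.4 H3K4me3/H3K4me1 log2-ratio exclusion, 12.5 kb stitching, 2-fold /
#' 0.5 RPKM somatic thresholds, 0.5 RPKM inactive floor, 100,000 background
#' regions, 10,000 permutations.
#'
#' @param ... Overrides.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    smooth_bins = 5L,        # ~250 bp moving average before candidate calling
    call_threshold_scale = 2, # genome-wide stringency on the q99 call threshold
    min_width = 200,
    background_n = 100000L,
    min_tss_dist = 2500,
    max_k4_ratio = 2.4,
    pseudocount = 0.1,
    stitch_gap = 12500,
    n_perm = 10000L,
    min_recurrent_pairs = 2L,
    fold_thresh = 2,
    diff_thresh = 0.5,
    inactive_rpkm = 0.5,
    promoter_flank = 500,
    cnv_gain = 0.6,
    cnv_loss = -1.0,
    min_trait_in = 10L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_se(paste("unknown config field(s):", paste(bad, collapse = ", ")),
                           "se_validation_error")
  cfg[names(over)] <- over
  cfg
}

#' @keywords internal
get_track <- function(ds, sample_id, mark) {
  tr <- ds$tracks[[paste(sample_id, mark, sep = "|")]]
  if (is.null(tr)) stop_se(sprintf("missing track %s|%s", sample_id, mark),
                           "se_pairing_error")
  tr
}

#' @keywords internal
dataset_pairs <- function(ds) {
  pts <- unique(ds$manifest$patient[ds$manifest$role == "tumor"])
  data.frame(patient = pts,
             tumor = vapply(pts, function(p)
               ds$manifest$sample_id[ds$manifest$patient == p &
                                       ds$manifest$role == "tumor"][1], ""),
             normal = vapply(pts, function(p)
               ds$manifest$sample_id[ds$manifest$patient == p &
                                       ds$manifest$role == "normal"][1], ""),
             stringsAsFactors = FALSE)
}

#' @keywords internal
fpkm_matrix <- function(ds) {
  m <- as.matrix(ds$fpkm[, -1, drop = FALSE])
  rownames(m) <- ds$fpkm$gene_id
  m
}

#' @keywords internal
beta_matrix <- function(ds) {
  m <- as.matrix(ds$beta[, -(1:3), drop = FALSE])
  rownames(m) <- ds$beta$probe_id
  m
}

#' Run the full somatic super-enhancer pipeline
#'
#' Calls candidate regions per cell line from smoothed input-corrected
#' H3K27ac, filters them to distal predicted enhancers, stitches and applies
#' the hockey-stick cutoff per line, merges the per-line super-enhancers
#' into a non-redundant catalog, scores recurrence by rank products,
#' classifies every catalog super-enhancer against the tumour/normal pairs,
#' assigns nearest active TSS, and computes the downstream expression,
#' methylation, copy-number, SNP, gene-set and TF statistics for which the
#' dataset has tables.
#'
#' @param ds An `se_dataset` (from [load_dataset()] or [generate_dataset()]).
#' @param cfg A [pipeline_config()] list.
#' @return A list of per-stage results (see the individual stage functions).
#' @export
run_pipeline <- function(ds, cfg = pipeline_config()) {
  genome <- ds$genome
  lines <- unique(ds$manifest$sample_id[ds$manifest$role == "cell_line"])
  if (length(lines) < 2) stop_se("need >= 2 cell lines", "se_validation_error")

  # aggregate H3K4me3 / H3K4me1 across all samples carrying those marks
  agg <- lapply(c("H3K4me3", "H3K4me1"), function(mk) {
    ids <- ds$manifest$sample_id[ds$manifest$mark == mk]
    aggregate_tracks(lapply(unique(ids), get_track, ds = ds, mark = mk), genome)
  })
  names(agg) <- c("H3K4me3", "H3K4me1")

  per_line <- list()
  for (li in seq_along(lines)) {
    s <- lines[li]
    chip <- get_track(ds, s, "H3K27ac")
    input <- get_track(ds, s, "input")
    bg <- build_background(chip, input, genome,
                           region_width = cfg$smooth_bins * genome$bin_size,
                           n = cfg$background_n, seed = cfg$seed + 1000L + li,
                           keep_values = FALSE, tail = "symmetric")
    signal <- corrected_bin_signal(chip, input, genome, cfg$smooth_bins)
    cand <- call_candidate_regions(signal, genome,
                                   cfg$call_threshold_scale * bg$threshold_p99,
                                   cfg$min_width)
    enh <- filter_to_predicted_enhancers(cand, ds$tss, agg$H3K4me3, agg$H3K4me1,
                                         genome, cfg$min_tss_dist,
                                         cfg$max_k4_ratio, cfg$pseudocount)
    st <- stitch(enh, cfg$stitch_gap)
    se_reg <- st$regions[0, , drop = FALSE]
    cut <- NULL
    if (nrow(st$regions) >= 3) {
      sig <- stitched_signal(st, enh, chip, input, genome)
      cut <- se_cutoff(sig)
      se_reg <- st$regions[cut$is_super, , drop = FALSE]
    }
    per_line[[s]] <- list(enhancers = enh, stitched = st, cutoff = cut,
                          super = se_reg, background = bg)
  }

  enhancer_catalog <- merge_catalog(lapply(per_line, `[[`, "enhancers"),
                                    id_prefix = "ENH")
  se_catalog <- merge_se_across_lines(lapply(per_line, `[[`, "super"))
  typical_catalog <- typical_enhancers(enhancer_catalog, se_catalog)

  # per-line corrected RPKM over the merged catalog: recurrence input
  line_rpkm <- sapply(lines, function(s) {
    corrected_rpkm(get_track(ds, s, "H3K27ac"), get_track(ds, s, "input"),
                   se_catalog, genome)
  })
  line_rpkm <- matrix(line_rpkm, nrow = nrow(se_catalog),
                      dimnames = list(se_catalog$id, lines))
  recurrence <- NULL
  if (nrow(se_catalog) >= 2) {
    recurrence <- rank_product_recurrence(line_rpkm, n_perm = cfg$n_perm,
                                          seed = cfg$seed + 2000L)
  }

  # somatic classification against the matched pairs
  pairs <- dataset_pairs(ds)
  somatic <- NULL
  if (nrow(pairs) >= 2 && nrow(se_catalog) > 0) {
    pair_rpkm <- function(samples) {
      m <- sapply(samples, function(s) {
        corrected_rpkm(get_track(ds, s, "H3K27ac"), get_track(ds, s, "input"),
                       se_catalog, genome)
      })
      matrix(m, nrow = nrow(se_catalog),
             dimnames = list(se_catalog$id, pairs$patient))
    }
    somatic <- classify_somatic(pair_rpkm(pairs$tumor), pair_rpkm(pairs$normal),
                                cfg$min_recurrent_pairs, cfg$fold_thresh,
                                cfg$diff_thresh, cfg$inactive_rpkm,
                                cfg$pseudocount)
  }

  # active promoters (any cell line above its own background) and gene links
  active <- rep(FALSE, nrow(ds$tss))
  prom_rpkm <- rep(0, nrow(ds$tss))
  for (li in seq_along(lines)) {
    s <- lines[li]
    chip <- get_track(ds, s, "H3K27ac")
    input <- get_track(ds, s, "input")
    bgp <- build_background(chip, input, genome,
                            region_width = 2 * cfg$promoter_flank,
                            n = cfg$background_n, seed = cfg$seed + 3000L + li,
                            keep_values = FALSE, tail = "symmetric")
    ap <- active_promoters(ds$tss, list(chip), list(input), genome, bgp,
                           flank = cfg$promoter_flank)
    active <- active | ap$active
    prom_rpkm <- pmax(prom_rpkm, ap$promoter_rpkm)
  }
  tss_active <- ds$tss
  tss_active$active <- active
  tss_active$promoter_rpkm <- prom_rpkm
  links <- if (nrow(se_catalog) > 0) assign_nearest_active(se_catalog, tss_active)
           else NULL

  out <- list(per_line = per_line, enhancers = enhancer_catalog,
              se_catalog = se_catalog, typical_catalog = typical_catalog,
              line_rpkm = line_rpkm, recurrence = recurrence,
              pairs = pairs, somatic = somatic, tss_active = tss_active,
              links = links)

  classes <- if (!is.null(somatic))
    stats::setNames(somatic$calls$class, somatic$calls$se_id) else NULL

  if (!is.null(ds$fpkm) && !is.null(links)) {
    fp <- fpkm_matrix(ds)
    expr_pairs <- data.frame(tumor = paste0("T_", pairs$patient),
                             normal = paste0("N_", pairs$patient))
    if (all(unlist(expr_pairs) %in% colnames(fp))) {
      out$expression <- expression_association(links, fp, expr_pairs, classes,
                                               cfg$pseudocount)
    }
  }
  if (!is.null(ds$beta) && !is.null(classes)) {
    bm <- beta_matrix(ds)
    meth_pairs <- data.frame(tumor = paste0("T_", pairs$patient),
                             normal = paste0("N_", pairs$patient))
    if (all(unlist(meth_pairs) %in% colnames(bm))) {
      probes <- ds$beta[, c("probe_id", "chrom", "pos")]
      out$methylation <- methylation_delta(se_catalog, probes, bm, meth_pairs,
                                           classes[se_catalog$id])
    }
  }
  if (!is.null(ds$cnv) && nrow(se_catalog) > 0) {
    lr <- sapply(pairs$patient, function(p) {
      seg <- ds$cnv[ds$cnv$patient == p, , drop = FALSE]
      suppressMessages(cnv_overlay(se_catalog, seg, cfg$cnv_gain,
                                   cfg$cnv_loss)$mean_log_ratio)
    })
    lr <- matrix(lr, nrow = nrow(se_catalog))
    mean_lr <- rowMeans(lr, na.rm = TRUE)
    status <- rep("neutral", nrow(se_catalog))
    status[!is.na(mean_lr) & mean_lr > cfg$cnv_gain] <- "gain"
    status[!is.na(mean_lr) & mean_lr < cfg$cnv_loss] <- "loss"
    out$cnv <- data.frame(se_id = se_catalog$id, mean_log_ratio = mean_lr,
                          status = status, stringsAsFactors = FALSE)
  }
  if (!is.null(ds$snps) && !is.null(classes)) {
    somatic_ids <- somatic$calls$se_id[somatic$calls$class %in% c("gain", "loss")]
    somatic_set <- se_catalog[se_catalog$id %in% somatic_ids, , drop = FALSE]
    if (nrow(somatic_set) > 0 && !is.null(ds$snps_background)) {
      out$snp_enrichment <- suppressMessages(
        snp_enrichment(ds$snps, ds$snps_background, somatic_set,
                       cfg$min_trait_in))
    }
  }
  if (!is.null(ds$genesets) && !is.null(links) && !is.null(classes)) {
    universe <- ds$tss$gene_id
    gain_genes <- unique(stats::na.omit(
      links$gene_id[classes[links$se_id] == "gain"]))
    if (length(gain_genes) > 0) {
      out$geneset_enrichment <- do.call(rbind, lapply(
        unique(ds$genesets$set_name), function(sn) {
          gs <- ds$genesets$gene_id[ds$genesets$set_name == sn]
          er <- geneset_enrichment(gain_genes, intersect(gs, universe), universe)
          data.frame(set_name = sn, n_overlap = er$n_overlap,
                     odds_ratio = er$odds_ratio, p_value = er$p_value,
                     stringsAsFactors = FALSE)
        }))
    }
  }
  if (!is.null(ds$tf_summits) && !is.null(classes)) {
    gain_set <- se_catalog[se_catalog$id %in%
                             somatic$calls$se_id[somatic$calls$class == "gain"], ,
                           drop = FALSE]
    unalt_set <- se_catalog[se_catalog$id %in%
                              somatic$calls$se_id[somatic$calls$class == "unaltered"], ,
                            drop = FALSE]
    tf_rows <- lapply(names(ds$tf_summits), function(tf) {
      sm <- ds$tf_summits[[tf]]
      data.frame(
        tf = tf,
        density_gain = if (nrow(gain_set)) tf_density(sm, gain_set)$density_per_mbp else NA,
        density_unaltered = if (nrow(unalt_set)) tf_density(sm, unalt_set)$density_per_mbp else NA,
        stringsAsFactors = FALSE)
    })
    out$tf_density <- do.call(rbind, tf_rows)
    if (length(ds$tf_summits) >= 2) {
      nms <- names(ds$tf_summits)[1:2]
      out$tf_cooccupancy <- cooccupancy(ds$tf_summits[[nms[1]]],
                                        ds$tf_summits[[nms[2]]])
    }
  }
  out
}
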