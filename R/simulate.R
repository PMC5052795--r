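#' Simulation design for the synthetic cohort
#'
#' Captures the stated world the generator emulates: a small two-chromosome
#' genome carrying enhancer-shaped peaks (high H3K27ac + H3K4me1, low
#' H3K4me3 distally; high H3K27ac + H3K4me3 at promoters of expressed
#' genes), constituent clusters stitchable within 12.5 kb, tumour/normal
#' fold effects per somatic class, and expression / methylation / TF-summit
#' / SNP couplings to the planted classes. All distributions are the
#' package's documented choices; defaults are chosen so planted effects
#' clear the pipeline's printed thresholds by construction.
#'
#' @param ... Overrides for any design field. Key fields and defaults:
#'   `n_cell_lines` (6), `n_pairs` (8), `chrom_lengths` (2 x 10 Mb),
#'   `bin_size` (50), `n_genes` (300), `frac_expressed` (0.75),
#'   `n_enhancer_clusters` (120), `se_fraction` (0.25),
#'   typical clusters: 1-3 constituents of 500-2000 bp, gaps 1000-12000 bp;
#'   super-enhancer clusters: 4-8 constituents of 1500-3000 bp, gaps
#'   1000-3000 bp; `peak_fold` (typical 10-20), `se_peak_fold` (30-60),
#'   `background_mean` (0.5 reads/bin), `dispersion` (NB size 10),
#'   `library_meanlog` (log 1e7), `library_sdlog` (0.15), `somatic_design`
#'   (fractions gain 0.35 / loss 0.20 / unaltered 0.25 / inactive 0.20;
#'   gain fold 3, loss fold 1/3), `affected_pair_prob` (0.6, min 3 pairs),
#'   `expression_coupling` (1), `methylation_coupling` (0.2),
#'   `tf_summit_rate` (1 per kb of gain-cluster constituent),
#'   `snp_enrichment_fold` (3), `n_background_snps` (20000),
#'   `n_trait_snps` (1200), `seed` (1).
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(...) {
  design <- list(
    n_cell_lines = 6L,
    n_pairs = 8L,
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
    bin_size = 50L,
    n_genes = 300L,
    frac_expressed = 0.75,
    min_tss_spacing = 4000,
    n_enhancer_clusters = 120L,
    se_fraction = 0.25,
    typical_constituents = c(1L, 3L),
    typical_width = c(500, 2000),
    typical_gap = c(1000, 12000),
    se_constituents = c(4L, 8L),
    se_width = c(1500, 3000),
    se_gap = c(1000, 3000),
    peak_fold = c(10, 20),
    se_peak_fold = c(30, 60),
    k4me1_fold = c(6, 12),
    promoter_fold = c(8, 16),
    tss_exclusion = 2500,
    cluster_separation = 13000, # > the 12.5 kb stitching distance
    background_mean = 0.5,
    dispersion = 10,
    library_meanlog = log(1e7),
    library_sdlog = 0.15,
    line_sdlog = 0.1,
    somatic_design = list(fractions = c(gain = 0.35, loss = 0.20,
                                        unaltered = 0.25, inactive = 0.20),
                          gain_fold = 3, loss_fold = 1 / 3),
    affected_pair_prob = 0.6,
    min_affected_pairs = 3L,
    expression_coupling = 1,
    expression_sdlog = 0.2,
    methylation_coupling = 0.2,
    methylation_sd = 0.05,
    probes_per_cluster = 8,
    n_background_probes = 300L,
    tf_summit_rate = 1,      # summits per kb of gain-cluster constituent
    tf_background_per_mb = 5,
    tf_cobind_prob = 0.75,
    tf_cobind_window = 300,
    snp_enrichment_fold = 3,
    n_background_snps = 20000L,
    n_trait_snps = 1200L,
    n_enriched_traits = 3L,
    n_null_traits = 2L,
    cnv_segment_mean_bp = 4e5,
    placement_retries = 10000L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(design))
  if (length(bad)) stop_se(paste("unknown design field(s):", paste(bad, collapse = ", ")),
                           "se_validation_error")
  design[names(over)] <- over
  fr <- design$somatic_design$fractions
  if (abs(sum(fr) - 1) > 1e-8) {
    stop_se("somatic_design fractions must sum to 1", "se_validation_error")
  }
  if (design$somatic_design$gain_fold < 2) {
    stop_se("gain fold must be >= 2 so planted effects exceed the classification threshold",
            "se_validation_error")
  }
  if (any(c(design$typical_width, design$se_width, design$typical_gap,
            design$se_gap) <= 0)) {
    stop_se("widths and gaps must be positive", "se_validation_error")
  }
  structure(design, class = "simulation_design")
}

# Snap a value to the bin grid.
snap_ <- function(x, bs) round(x / bs) * bs

#' Generate a synthetic dataset with planted ground truth
#'
#' Produces a complete in-memory dataset in the layout [load_dataset()]
#' consumes, plus a ground-truth object for recovery scoring. Identical
#' seeds yield identical datasets; [write_dataset()] writes byte-identical
#' files.
#'
#' @param design A `simulation_design`.
#' @return List with `dataset` (class `se_dataset`) and `truth` (class
#'   `ground_truth`).
#' @export
generate_dataset <- function(design = simulation_design()) {
  with_seed_(design$seed, generate_dataset_impl(design))
}

generate_dataset_impl <- function(design) {
  genome <- genome_model(design$chrom_lengths, design$bin_size)
  bs <- genome$bin_size
  nb <- n_bins(genome)
  G <- sum(genome$chroms)

  ## --- genes -------------------------------------------------------------
  tss <- place_tss(design, genome)

  ## --- enhancer clusters -------------------------------------------------
  pl <- place_clusters(design, genome, tss)
  clusters <- pl$clusters
  constituents <- pl$constituents

  ## --- somatic classes and per-pair effects -------------------------------
  ncl <- nrow(clusters)
  fr <- design$somatic_design$fractions
  n_per <- stats::setNames(floor(fr * ncl), names(fr))
  rem <- ncl - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1
  clusters$class <- sample(rep(names(n_per), n_per))
  pair_ids <- sprintf("P%02d", seq_len(design$n_pairs))
  fold_of <- c(gain = design$somatic_design$gain_fold,
               loss = design$somatic_design$loss_fold)
  affected <- matrix(FALSE, ncl, design$n_pairs,
                     dimnames = list(clusters$cluster_id, pair_ids))
  pair_fold <- matrix(1, ncl, design$n_pairs,
                      dimnames = list(clusters$cluster_id, pair_ids))
  for (i in seq_len(ncl)) {
    if (clusters$class[i] %in% c("gain", "loss")) {
      aff <- stats::runif(design$n_pairs) < design$affected_pair_prob
      need <- min(design$min_affected_pairs, design$n_pairs)
      while (sum(aff) < need) {
        off <- which(!aff)
        aff[off[sample.int(length(off), 1)]] <- TRUE
      }
      affected[i, ] <- aff
      pair_fold[i, aff] <- fold_of[[clusters$class[i]]]
    }
  }

  ## --- constituent peak folds ---------------------------------------------
  is_se_row <- clusters$is_super[constituents$cluster_idx]
  constituents$k27_fold <- ifelse(
    is_se_row,
    stats::runif(nrow(constituents), design$se_peak_fold[1], design$se_peak_fold[2]),
    stats::runif(nrow(constituents), design$peak_fold[1], design$peak_fold[2]))
  constituents$k4me1_fold <- stats::runif(nrow(constituents),
                                          design$k4me1_fold[1], design$k4me1_fold[2])
  tss$prom_k27_fold <- ifelse(tss$expressed,
                              stats::runif(nrow(tss), design$promoter_fold[1],
                                           design$promoter_fold[2]), 1)
  tss$prom_k4me3_fold <- ifelse(tss$expressed,
                                stats::runif(nrow(tss), design$promoter_fold[1],
                                             design$promoter_fold[2]), 1)

  line_ids <- sprintf("CL%d", seq_len(design$n_cell_lines))
  line_mult <- matrix(stats::rlnorm(ncl * design$n_cell_lines, 0, design$line_sdlog),
                      ncl, design$n_cell_lines,
                      dimnames = list(clusters$cluster_id, line_ids))

  ## --- samples and tracks --------------------------------------------------
  manifest <- build_manifest(design, line_ids, pair_ids)
  manifest$library_size <- round(stats::rlnorm(nrow(manifest),
                                               design$library_meanlog,
                                               design$library_sdlog))
  lib_ref <- exp(design$library_meanlog)
  tracks <- list()
  for (r in seq_len(nrow(manifest))) {
    m <- manifest[r, ]
    fold <- fold_profile(m, genome, clusters, constituents, tss,
                         line_mult, pair_fold, design)
    bins <- list()
    for (chrom in names(nb)) {
      mu <- design$background_mean * (m$library_size / lib_ref) * fold[[chrom]]
      bins[[chrom]] <- stats::rnbinom(nb[[chrom]], mu = mu,
                                      size = design$dispersion)
    }
    tracks[[paste(m$sample_id, m$mark, sep = "|")]] <-
      signal_track(m$sample_id, m$mark, m$library_size, bins, genome)
  }

  ## --- link clusters to nearest expressed gene -----------------------------
  center <- floor((clusters$start + clusters$end) / 2)
  clusters$linked_gene <- vapply(seq_len(ncl), function(i) {
    cand <- tss[tss$chrom == clusters$chrom[i] & tss$expressed, , drop = FALSE]
    cand <- cand[order(cand$pos), , drop = FALSE]
    d <- abs(cand$pos - center[i])
    cand$gene_id[which(d == min(d))[1]]
  }, "")

  ## --- expression ----------------------------------------------------------
  tss$baseline_fpkm <- ifelse(tss$expressed,
                              stats::rlnorm(nrow(tss), log(10), 0.7),
                              stats::runif(nrow(tss), 0, 0.05))
  gene_pair_fold <- matrix(1, nrow(tss), design$n_pairs,
                           dimnames = list(tss$gene_id, pair_ids))
  seen <- character(0)
  for (i in seq_len(ncl)) {
    g <- clusters$linked_gene[i]
    if (g %in% seen || !clusters$class[i] %in% c("gain", "loss")) next
    seen <- c(seen, g)
    gene_pair_fold[g, affected[i, ]] <-
      fold_of[[clusters$class[i]]]^design$expression_coupling
  }
  noise <- function(n) stats::rlnorm(n, 0, design$expression_sdlog)
  fpkm <- matrix(NA_real_, nrow(tss),
                 design$n_cell_lines + 2 * design$n_pairs)
  cl_cols <- line_ids
  t_cols <- paste0("T_", pair_ids); n_cols <- paste0("N_", pair_ids)
  colnames(fpkm) <- c(cl_cols, t_cols, n_cols)
  rownames(fpkm) <- tss$gene_id
  for (s in cl_cols) fpkm[, s] <- tss$baseline_fpkm * noise(nrow(tss))
  for (j in seq_len(design$n_pairs)) {
    nrm <- tss$baseline_fpkm * noise(nrow(tss))
    fpkm[, n_cols[j]] <- nrm
    fpkm[, t_cols[j]] <- nrm * gene_pair_fold[, j] * noise(nrow(tss))
  }

  ## --- methylation ---------------------------------------------------------
  meth <- make_methylation(design, genome, clusters, affected, pair_ids)

  ## --- TF summits ----------------------------------------------------------
  tf <- make_tf_summits(design, genome, clusters, constituents)

  ## --- SNPs ----------------------------------------------------------------
  snps <- make_snps(design, genome, clusters)

  ## --- copy number ---------------------------------------------------------
  cnv <- make_cnv(design, genome, pair_ids)

  ## --- gene sets -----------------------------------------------------------
  gain_genes <- unique(clusters$linked_gene[clusters$class == "gain"])
  genesets <- make_genesets(tss$gene_id, gain_genes)

  ds <- structure(list(
    genome = genome,
    config = list(genome = list(chrom = names(genome$chroms),
                                length = unname(genome$chroms)),
                  bin_size = bs, seed = design$seed),
    manifest = manifest, tracks = tracks,
    tss = tss[, c("gene_id", "chrom", "pos", "strand")],
    fpkm = data.frame(gene_id = rownames(fpkm), fpkm,
                      stringsAsFactors = FALSE, check.names = FALSE),
    beta = meth$beta_df,
    snps = snps$trait, snps_background = snps$background,
    cnv = cnv, genesets = genesets,
    tf_summits = tf), class = "se_dataset")

  truth <- structure(list(
    design = design,
    clusters = clusters,
    constituents = constituents,
    affected = affected, pair_fold = pair_fold, line_mult = line_mult,
    tss = tss,
    gene_pair_fold = gene_pair_fold,
    delta_beta = meth$delta_truth,
    somatic_extent_bp = snps$somatic_bp), class = "ground_truth")

  list(dataset = ds, truth = truth)
}

place_tss <- function(design, genome, max_tries = 50000L) {
  bs <- genome$bin_size
  pos <- numeric(0); chrom <- character(0)
  tries <- 0
  while (length(pos) < design$n_genes && tries < max_tries) {
    tries <- tries + 1
    cm <- sample(names(genome$chroms), 1, prob = genome$chroms)
    p <- snap_(stats::runif(1, 1e4, genome$chroms[[cm]] - 1e4), bs)
    same <- chrom == cm
    if (!any(same) || min(abs(pos[same] - p)) >= design$min_tss_spacing) {
      pos <- c(pos, p); chrom <- c(chrom, cm)
    }
  }
  if (length(pos) < design$n_genes) {
    stop_se("could not place TSS annotations", "se_placement_error")
  }
  tss <- data.frame(gene_id = sprintf("gene_%04d", seq_len(design$n_genes)),
                    chrom = chrom, pos = pos,
                    strand = sample(c("+", "-"), design$n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  tss$expressed <- stats::runif(design$n_genes) < design$frac_expressed
  tss
}

place_clusters <- function(design, genome, tss) {
  bs <- genome$bin_size
  ncl <- design$n_enhancer_clusters
  n_se <- round(ncl * design$se_fraction)
  is_super <- sample(c(rep(TRUE, n_se), rep(FALSE, ncl - n_se)))
  cl_rows <- list(); const_rows <- list()
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  for (i in seq_len(ncl)) {
    if (is_super[i]) {
      k <- sample(design$se_constituents[1]:design$se_constituents[2], 1)
      w <- snap_(stats::runif(k, design$se_width[1], design$se_width[2]), bs)
      g <- snap_(stats::runif(max(k - 1, 0), design$se_gap[1], design$se_gap[2]), bs)
    } else {
      k <- sample(design$typical_constituents[1]:design$typical_constituents[2], 1)
      w <- snap_(stats::runif(k, design$typical_width[1], design$typical_width[2]), bs)
      g <- snap_(stats::runif(max(k - 1, 0), design$typical_gap[1], design$typical_gap[2]), bs)
    }
    span <- sum(w) + sum(g)
    ok <- FALSE
    for (try in seq_len(design$placement_retries)) {
      cm <- sample(names(genome$chroms), 1, prob = genome$chroms)
      if (genome$chroms[[cm]] - span - 2e4 < 2e4) next
      st <- snap_(stats::runif(1, 1e4, genome$chroms[[cm]] - span - 1e4), bs)
      offs <- cumsum(c(0, head(w, -1) + g))
      cs <- st + offs; ce <- cs + w
      # distal constraint: the whole extent (constituents and gaps) keeps
      # 2.5 kb clear of every TSS, so no promoter peak contaminates the span
      ereg <- regions(cm, st, st + span)
      if (min(distance_to_nearest_tss(ereg, tss)) < design$tss_exclusion) next
      # separation from already placed cluster extents
      same <- placed[placed$chrom == cm, , drop = FALSE]
      if (nrow(same) > 0 &&
          any(st < same$end + design$cluster_separation &
              same$start < st + span + design$cluster_separation)) next
      placed <- rbind(placed, data.frame(chrom = cm, start = st, end = st + span))
      cl_rows[[i]] <- data.frame(
        cluster_id = sprintf("cluster_%03d", i), chrom = cm,
        start = st, end = st + span, is_super = is_super[i],
        n_constituents = k, stringsAsFactors = FALSE)
      const_rows[[i]] <- data.frame(
        cluster_idx = i, cluster_id = sprintf("cluster_%03d", i),
        chrom = cm, start = cs, end = ce, stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop_se(sprintf("could not place cluster %d after %d retries", i,
                      design$placement_retries), "se_placement_error")
    }
  }
  list(clusters = do.call(rbind, cl_rows),
       constituents = do.call(rbind, const_rows))
}

build_manifest <- function(design, line_ids, pair_ids) {
  rows <- list()
  for (s in line_ids) {
    for (mk in c("H3K27ac", "H3K4me1", "H3K4me3", "input")) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, patient = s, role = "cell_line", mark = mk,
        stringsAsFactors = FALSE)
    }
  }
  for (p in pair_ids) {
    for (role in c("tumor", "normal")) {
      sid <- paste0(ifelse(role == "tumor", "T_", "N_"), p)
      for (mk in c("H3K27ac", "input")) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, patient = p, role = role, mark = mk,
          stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(rbind, rows)
  m$path <- sprintf("tracks/%s_%s.bedGraph", m$sample_id, m$mark)
  m
}

# Per-sample, per-mark multiplicative fold profile over the genome bins.
fold_profile <- function(m, genome, clusters, constituents, tss,
                         line_mult, pair_fold, design) {
  nb <- n_bins(genome)
  bs <- genome$bin_size
  fold <- lapply(nb, function(n) rep(1, n))
  if (m$mark == "input") return(fold)
  paint <- function(fold, chrom, start, end, value) {
    b0 <- start %/% bs + 1
    b1 <- ceiling(end / bs)
    fold[[chrom]][b0:b1] <- value
    fold
  }
  # constituent peaks: H3K27ac and H3K4me1
  if (m$mark %in% c("H3K27ac", "H3K4me1")) {
    for (r in seq_len(nrow(constituents))) {
      ci <- constituents$cluster_idx[r]
      cls <- clusters$class[ci]
      base <- if (m$mark == "H3K27ac") constituents$k27_fold[r]
              else constituents$k4me1_fold[r]
      f <- if (m$role == "cell_line") {
        base * line_mult[ci, m$sample_id]
      } else if (cls == "inactive") {
        1
      } else if (m$role == "tumor") {
        base * pair_fold[ci, m$patient]
      } else {
        base
      }
      if (f != 1) {
        fold <- paint(fold, constituents$chrom[r], constituents$start[r],
                      constituents$end[r], f)
      }
    }
  }
  # promoter peaks: H3K27ac and H3K4me3 at expressed genes
  if (m$mark %in% c("H3K27ac", "H3K4me3")) {
    expr <- tss[tss$expressed, , drop = FALSE]
    for (r in seq_len(nrow(expr))) {
      f <- if (m$mark == "H3K27ac") expr$prom_k27_fold[r] else expr$prom_k4me3_fold[r]
      lo <- max(expr$pos[r] - 500, 0)
      hi <- min(expr$pos[r] + 500, genome$chroms[[expr$chrom[r]]])
      fold <- paint(fold, expr$chrom[r], lo, hi, f)
    }
  }
  fold
}

make_methylation <- function(design, genome, clusters, affected, pair_ids) {
  ncl <- nrow(clusters)
  rows <- list()
  for (i in seq_len(ncl)) {
    np <- 3 + stats::rpois(1, design$probes_per_cluster - 3)
    pos <- sort(floor(stats::runif(np, clusters$start[i], clusters$end[i] - 1)))
    rows[[i]] <- data.frame(chrom = clusters$chrom[i], pos = pos,
                            cluster_idx = i, stringsAsFactors = FALSE)
  }
  bg_chrom <- sample(names(genome$chroms), design$n_background_probes,
                     replace = TRUE, prob = genome$chroms)
  rows[[ncl + 1]] <- data.frame(
    chrom = bg_chrom,
    pos = floor(stats::runif(design$n_background_probes) * genome$chroms[bg_chrom]),
    cluster_idx = NA_integer_, stringsAsFactors = FALSE)
  probes <- do.call(rbind, rows)
  probes$probe_id <- sprintf("probe_%05d", seq_len(nrow(probes)))
  base <- stats::runif(nrow(probes), 0.3, 0.7)
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  np <- nrow(probes); npair <- length(pair_ids)
  beta <- matrix(NA_real_, np, 2 * npair)
  colnames(beta) <- c(paste0("T_", pair_ids), paste0("N_", pair_ids))
  delta_truth <- rep(0, np)
  cls <- clusters$class[probes$cluster_idx]
  delta_truth[!is.na(cls) & cls == "gain"] <- -design$methylation_coupling
  delta_truth[!is.na(cls) & cls == "loss"] <- design$methylation_coupling
  for (j in seq_len(npair)) {
    nrm <- clip01(base + stats::rnorm(np, 0, design$methylation_sd))
    aff <- !is.na(probes$cluster_idx) & affected[cbind(
      pmax(probes$cluster_idx, 1), j)]
    tum <- clip01(base + ifelse(aff, delta_truth, 0) +
                    stats::rnorm(np, 0, design$methylation_sd))
    beta[, paste0("N_", pair_ids[j])] <- nrm
    beta[, paste0("T_", pair_ids[j])] <- tum
  }
  beta_df <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                        pos = probes$pos, beta, stringsAsFactors = FALSE,
                        check.names = FALSE)
  list(beta_df = beta_df,
       delta_truth = data.frame(probe_id = probes$probe_id,
                                cluster_idx = probes$cluster_idx,
                                delta = delta_truth, stringsAsFactors = FALSE))
}

make_tf_summits <- function(design, genome, clusters, constituents) {
  gain_const <- constituents[clusters$class[constituents$cluster_idx] == "gain", ,
                             drop = FALSE]
  tfa_pos <- numeric(0); tfa_chrom <- character(0)
  for (r in seq_len(nrow(gain_const))) {
    kb <- (gain_const$end[r] - gain_const$start[r]) / 1000
    n <- stats::rpois(1, design$tf_summit_rate * kb)
    if (n > 0) {
      tfa_pos <- c(tfa_pos, floor(stats::runif(n, gain_const$start[r],
                                               gain_const$end[r] - 1)))
      tfa_chrom <- c(tfa_chrom, rep(gain_const$chrom[r], n))
    }
  }
  bg_n <- stats::rpois(1, design$tf_background_per_mb * sum(genome$chroms) / 1e6)
  bg_chrom <- sample(names(genome$chroms), bg_n, replace = TRUE,
                     prob = genome$chroms)
  bg_pos <- floor(stats::runif(bg_n) * (genome$chroms[bg_chrom] - 1))
  tfa <- data.frame(chrom = c(tfa_chrom, bg_chrom), pos = c(tfa_pos, bg_pos),
                    stringsAsFactors = FALSE)
  co <- stats::runif(nrow(tfa)) < design$tf_cobind_prob
  tfb_pos <- tfa$pos[co] + round(stats::runif(sum(co), -design$tf_cobind_window,
                                              design$tf_cobind_window))
  tfb_pos <- pmin(pmax(tfb_pos, 0), genome$chroms[tfa$chrom[co]] - 1)
  bgb_n <- stats::rpois(1, design$tf_background_per_mb * sum(genome$chroms) / 1e6)
  bgb_chrom <- sample(names(genome$chroms), bgb_n, replace = TRUE,
                      prob = genome$chroms)
  tfb <- data.frame(chrom = c(tfa$chrom[co], bgb_chrom),
                    pos = c(tfb_pos, floor(stats::runif(bgb_n) *
                                             (genome$chroms[bgb_chrom] - 1))),
                    stringsAsFactors = FALSE)
  as_summits <- function(df, prefix) {
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    regions(df$chrom, df$pos, df$pos + 1,
            id = sprintf("%s_%05d", prefix, seq_len(nrow(df))))
  }
  list(TFA = as_summits(tfa, "TFA"), TFB = as_summits(tfb, "TFB"))
}

make_snps <- function(design, genome, clusters) {
  G <- sum(genome$chroms)
  somatic <- clusters[clusters$class %in% c("gain", "loss"), , drop = FALSE]
  A <- sum(somatic$end - somatic$start)
  uniform_snps <- function(n) {
    cm <- sample(names(genome$chroms), n, replace = TRUE, prob = genome$chroms)
    data.frame(chrom = cm, pos = floor(stats::runif(n) * (genome$chroms[cm] - 1)),
               stringsAsFactors = FALSE)
  }
  in_somatic_snps <- function(n) {
    w <- somatic$end - somatic$start
    idx <- sample(seq_len(nrow(somatic)), n, replace = TRUE, prob = w)
    data.frame(chrom = somatic$chrom[idx],
               pos = floor(stats::runif(n, somatic$start[idx], somatic$end[idx] - 1)),
               stringsAsFactors = FALSE)
  }
  bg <- uniform_snps(design$n_background_snps)
  bg$id <- sprintf("bg_snp_%05d", seq_len(nrow(bg)))
  trait_rows <- list()
  q <- (design$snp_enrichment_fold - 1) * A / G
  q <- q / (1 + q)
  for (t in seq_len(design$n_enriched_traits + design$n_null_traits)) {
    enriched <- t <= design$n_enriched_traits
    nm <- if (enriched) sprintf("trait_enriched_%d", t)
          else sprintf("trait_null_%d", t - design$n_enriched_traits)
    n <- design$n_trait_snps
    if (enriched && A > 0) {
      inside <- stats::runif(n) < q
      df <- rbind(in_somatic_snps(sum(inside)), uniform_snps(sum(!inside)))
    } else {
      df <- uniform_snps(n)
    }
    df$id <- sprintf("%s_snp_%05d", nm, seq_len(n))
    df$trait <- nm
    trait_rows[[t]] <- df
  }
  trait <- do.call(rbind, trait_rows)
  rownames(trait) <- NULL
  list(trait = trait[, c("chrom", "pos", "id", "trait")],
       background = bg[, c("chrom", "pos", "id")],
       somatic_bp = A)
}

make_cnv <- function(design, genome, pair_ids) {
  rows <- list()
  for (p in pair_ids) {
    for (cm in names(genome$chroms)) {
      len <- genome$chroms[[cm]]
      n_seg <- max(2, stats::rpois(1, len / design$cnv_segment_mean_bp))
      cuts <- sort(sample(seq(1e4, len - 1e4, by = 1e4), n_seg - 1))
      st <- c(0, cuts); en <- c(cuts, len)
      cls <- sample(c("neutral", "gain", "loss"), n_seg, replace = TRUE,
                    prob = c(0.9, 0.05, 0.05))
      lr <- ifelse(cls == "gain", stats::rnorm(n_seg, 0.9, 0.1),
                   ifelse(cls == "loss", stats::rnorm(n_seg, -1.3, 0.1),
                          stats::rnorm(n_seg, 0, 0.2)))
      rows[[length(rows) + 1]] <- data.frame(
        patient = p, chrom = cm, start = st, end = en, log_ratio = round(lr, 4),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

make_genesets <- function(all_genes, gain_genes, n_sets = 10L, set_size = 30L) {
  set_size <- min(set_size, max(floor(length(all_genes) / 3), 2))
  rows <- list()
  for (k in seq_len(n_sets)) {
    nm <- sprintf("hallmark_%02d", k)
    if (k == 1) {
      # one set planted to be enriched for gain-linked genes
      core <- gain_genes[stats::runif(length(gain_genes)) < 0.6]
      pool <- setdiff(all_genes, core)
      fill <- sample(pool, min(max(set_size - length(core), 5), length(pool)))
      members <- c(core, fill)
    } else {
      members <- sample(all_genes, set_size)
    }
    rows[[k]] <- data.frame(set_name = nm, gene_id = members,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a dataset (and optional ground truth) to disk
#'
#' Emits the exact layout [load_dataset()] consumes: `config.json`,
#' `manifest.tsv`, per-track bedGraphs under `tracks/`, `tss.tsv` and the
#' optional tables; SNP positions are converted to their on-disk 1-based
#' convention. With `truth`, also writes `truth/*.tsv`.
#'
#' @param ds An `se_dataset`.
#' @param dir Output directory.
#' @param truth Optional `ground_truth`.
#' @return Invisible `dir`.
#' @export
write_dataset <- function(ds, dir, truth = NULL) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(ds$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_(ds$manifest, file.path(dir, "manifest.tsv"))
  for (i in seq_len(nrow(ds$manifest))) {
    m <- ds$manifest[i, ]
    write_bedgraph_track(ds$tracks[[paste(m$sample_id, m$mark, sep = "|")]],
                         ds$genome, file.path(dir, m$path))
  }
  write_tsv_(ds$tss, file.path(dir, "tss.tsv"))
  for (nm in c("fpkm", "beta", "cnv", "genesets")) {
    if (!is.null(ds[[nm]])) write_tsv_(ds[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  if (!is.null(ds$snps)) {
    out <- ds$snps; out$pos <- out$pos + 1 # 1-based on disk
    write_tsv_(out, file.path(dir, "snps.tsv"))
  }
  if (!is.null(ds$snps_background)) {
    out <- ds$snps_background; out$pos <- out$pos + 1
    write_tsv_(out, file.path(dir, "snps_background.tsv"))
  }
  for (nm in names(ds$tf_summits)) {
    write_bed(ds$tf_summits[[nm]], file.path(dir, sprintf("tf_%s.bed", nm)))
  }
  if (!is.null(truth)) {
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    write_tsv_(truth$clusters, file.path(dir, "truth", "clusters.tsv"))
    write_tsv_(truth$constituents, file.path(dir, "truth", "constituents.tsv"))
    aff <- data.frame(cluster_id = rownames(truth$affected), truth$affected,
                      check.names = FALSE)
    write_tsv_(aff, file.path(dir, "truth", "affected_pairs.tsv"))
  }
  invisible(dir)
}

#' Match two region sets by reciprocal overlap
#'
#' Pairs regions whose mutual overlap covers at least `min_frac` of each
#' region; when several calls match one truth region the pair with the
#' largest Jaccard index wins (one-to-one matching).
#'
#' @param truth_reg,call_reg Region data.frames.
#' @param min_frac Reciprocal overlap fraction (default 0.5).
#' @return data.frame: truth_idx, call_idx, jaccard.
#' @export
match_regions <- function(truth_reg, call_reg, min_frac = 0.5) {
  empty <- data.frame(truth_idx = integer(0), call_idx = integer(0),
                      jaccard = numeric(0))
  if (nrow(truth_reg) == 0 || nrow(call_reg) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges(truth_reg), as_granges(call_reg))
  if (length(hits) == 0) return(empty)
  ti <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
  ov <- pmin(truth_reg$end[ti], call_reg$end[ci]) -
    pmax(truth_reg$start[ti], call_reg$start[ci])
  wt <- truth_reg$end[ti] - truth_reg$start[ti]
  wc <- call_reg$end[ci] - call_reg$start[ci]
  keep <- ov >= min_frac * wt & ov >= min_frac * wc
  df <- data.frame(truth_idx = ti[keep], call_idx = ci[keep],
                   jaccard = (ov / (wt + wc - ov))[keep])
  df <- df[order(-df$jaccard), , drop = FALSE]
  df <- df[!duplicated(df$truth_idx) & !duplicated(df$call_idx), , drop = FALSE]
  df[order(df$truth_idx), , drop = FALSE]
}

#' Score pipeline calls against planted ground truth
#'
#' Matches calls to planted regions by >= 50% reciprocal overlap and reports
#' per-stage precision/recall, Jaccard indices, the somatic-class confusion
#' matrix and linked-gene accuracy. Precision is NA when there are no calls.
#'
#' @param truth A `ground_truth`.
#' @param calls Pipeline outputs: any of `enhancers`, `se_catalog`,
#'   `somatic` (a `somatic_calls`), `links` (gene-link table).
#' @return List of class `truth_report` with per-stage metrics.
#' @export
truth_report <- function(truth, calls) {
  pr <- function(n_match, n_truth, n_call) {
    list(recall = if (n_truth > 0) n_match / n_truth else NA_real_,
         precision = if (n_call > 0) n_match / n_call else NA_real_)
  }
  out <- list()
  if (!is.null(calls$enhancers)) {
    m <- match_regions(truth$constituents, calls$enhancers)
    out$enhancers <- c(pr(nrow(m), nrow(truth$constituents), nrow(calls$enhancers)),
                       list(mean_jaccard = mean(m$jaccard)))
  }
  se_truth <- truth$clusters[truth$clusters$is_super, , drop = FALSE]
  se_match <- NULL
  if (!is.null(calls$se_catalog)) {
    se_match <- match_regions(se_truth, calls$se_catalog)
    out$super_enhancers <- c(pr(nrow(se_match), nrow(se_truth),
                                nrow(calls$se_catalog)),
                             list(mean_jaccard = mean(se_match$jaccard),
                                  min_jaccard = suppressWarnings(min(se_match$jaccard))))
  }
  if (!is.null(calls$somatic) && !is.null(se_match) && nrow(se_match) > 0) {
    calls_df <- if (inherits(calls$somatic, "somatic_calls")) calls$somatic$calls
                else calls$somatic
    truth_cls <- se_truth$class[se_match$truth_idx]
    called_ids <- calls$se_catalog$id[se_match$call_idx]
    called_cls <- calls_df$class[match(called_ids, calls_df$se_id)]
    lv <- c("gain", "loss", "unaltered", "inactive")
    conf <- table(truth = factor(truth_cls, lv), called = factor(called_cls, lv))
    out$somatic <- list(confusion = conf,
                        accuracy = sum(diag(conf)) / sum(conf))
  }
  if (!is.null(calls$links) && !is.null(se_match) && nrow(se_match) > 0) {
    truth_gene <- se_truth$linked_gene[se_match$truth_idx]
    called_ids <- calls$se_catalog$id[se_match$call_idx]
    called_gene <- calls$links$gene_id[match(called_ids, calls$links$se_id)]
    out$gene_links <- list(accuracy = mean(truth_gene == called_gene, na.rm = TRUE),
                           n_compared = sum(!is.na(called_gene)))
  }
  structure(out, class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ":\n", sep = "")
    el <- x[[nm]]
    for (f in names(el)) {
      if (is.table(el[[f]])) { print(el[[f]]) }
      else cat(sprintf("  %s: %s\n", f, paste(signif(unlist(el[[f]]), 4), collapse = " ")))
    }
  }
  invisible(x)
}
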