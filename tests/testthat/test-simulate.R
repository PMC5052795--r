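test_that("identical seeds give byte-identical written datasets", {
  d <- simulation_design(chrom_lengths = c(chr1 = 1e6), n_genes = 25,
                         n_enhancer_clusters = 8, n_cell_lines = 2, n_pairs = 2,
                         n_background_snps = 1500, n_trait_snps = 120,
                         n_background_probes = 50, seed = 99)
  hash_dir <- function() {
    dir <- tempfile()
    sim <- generate_dataset(d)
    write_dataset(sim$dataset, dir, truth = sim$truth)
    files <- list.files(dir, recursive = TRUE, full.names = TRUE)
    setNames(tools::md5sum(files), list.files(dir, recursive = TRUE))
  }
  h1 <- hash_dir(); h2 <- hash_dir()
  expect_identical(h1, h2)
  expect_gt(length(h1), 10)
})

test_that("the generator books exactly the designed number of clusters", {
  sim <- generate_dataset(small_design(seed = 2))
  expect_equal(nrow(sim$truth$clusters), 30)
  expect_equal(sum(sim$truth$clusters$is_super), round(30 * 0.25))
  expect_setequal(unique(sim$truth$clusters$class),
                  c("gain", "loss", "unaltered", "inactive"))
  # somatic fractions of the design are respected up to rounding
  tab <- table(sim$truth$clusters$class)
  expect_true(all(abs(tab / 30 - c(gain = 0.35, inactive = 0.20, loss = 0.20,
                                   unaltered = 0.25)[names(tab)]) <= 0.05))
})

test_that("planted tumour/normal RPKM ratio over gain clusters matches the design", {
  d <- small_design(seed = 5, background_mean = 20)
  sim <- generate_dataset(d)
  ds <- sim$dataset; tr <- sim$truth
  gm <- ds$genome
  gain_idx <- which(tr$clusters$class == "gain")
  ratios <- c()
  for (i in gain_idx) {
    const <- tr$constituents[tr$constituents$cluster_idx == i, , drop = FALSE]
    creg <- regions(const$chrom, const$start, const$end)
    for (p in colnames(tr$affected)[tr$affected[i, ]]) {
      t_rpkm <- compute_rpkm(ds$tracks[[paste0("T_", p, "|H3K27ac")]], creg, gm)
      n_rpkm <- compute_rpkm(ds$tracks[[paste0("N_", p, "|H3K27ac")]], creg, gm)
      ratios <- c(ratios, sum(t_rpkm) / sum(n_rpkm))
    }
  }
  expect_equal(mean(ratios), 3, tolerance = 0.1)
})

test_that("planted geometry honours the distal and stitching invariants", {
  sim <- generate_dataset(small_design(seed = 6))
  tr <- sim$truth
  creg <- regions(tr$constituents$chrom, tr$constituents$start,
                  tr$constituents$end)
  # constituents at least 2.5 kb from every TSS
  expect_true(all(distance_to_nearest_tss(creg, tr$tss) >= 2500))
  # consecutive constituents within a cluster are stitchable (<= 12 kb apart)
  for (i in unique(tr$constituents$cluster_idx)) {
    cc <- tr$constituents[tr$constituents$cluster_idx == i, , drop = FALSE]
    if (nrow(cc) > 1) {
      expect_true(all(cc$start[-1] - cc$end[-nrow(cc)] <= 12000))
    }
  }
  # distinct cluster extents are separated by more than 12.5 kb
  cl <- tr$clusters[order(tr$clusters$chrom, tr$clusters$start), ]
  same <- cl$chrom[-1] == cl$chrom[-nrow(cl)]
  gaps <- (cl$start[-1] - cl$end[-nrow(cl)])[same]
  expect_true(all(gaps > 12500))
})

test_that("aggregate H3K4me3/H3K4me1 log-ratio separates enhancers from promoters", {
  sim <- generate_dataset(small_design(seed = 8))
  ds <- sim$dataset; tr <- sim$truth; gm <- ds$genome
  lines <- unique(ds$manifest$sample_id[ds$manifest$role == "cell_line"])
  agg <- function(mk) aggregate_tracks(lapply(lines, function(s)
    ds$tracks[[paste(s, mk, sep = "|")]]), gm)
  k4me3 <- agg("H3K4me3"); k4me1 <- agg("H3K4me1")
  lr <- function(reg) {
    log2((compute_rpkm(k4me3, reg, gm) + 0.1) /
           (compute_rpkm(k4me1, reg, gm) + 0.1))
  }
  creg <- regions(tr$constituents$chrom, tr$constituents$start, tr$constituents$end)
  expect_true(all(lr(creg) < 2.4))
  expr <- tr$tss[tr$tss$expressed, ]
  prom <- regions(expr$chrom, expr$pos - 500, expr$pos + 500)
  expect_true(mean(lr(prom) > 2.4) > 0.95)
})

test_that("truth_report handles the identity and degenerate cases", {
  sim <- generate_dataset(small_design(seed = 9))
  tr <- sim$truth
  se <- tr$clusters[tr$clusters$is_super, , drop = FALSE]
  se_reg <- regions(se$chrom, se$start, se$end, id = se$cluster_id)
  ideal <- list(
    enhancers = regions(tr$constituents$chrom, tr$constituents$start,
                        tr$constituents$end),
    se_catalog = se_reg,
    somatic = data.frame(se_id = se$cluster_id, class = se$class),
    links = data.frame(se_id = se$cluster_id, gene_id = se$linked_gene))
  rep1 <- truth_report(tr, ideal)
  expect_equal(rep1$enhancers$recall, 1)
  expect_equal(rep1$enhancers$precision, 1)
  expect_equal(rep1$super_enhancers$mean_jaccard, 1)
  expect_equal(rep1$somatic$accuracy, 1)
  expect_equal(rep1$gene_links$accuracy, 1)
  empty <- list(enhancers = regions(character(0), numeric(0), numeric(0)),
                se_catalog = regions(character(0), numeric(0), numeric(0)))
  rep0 <- truth_report(tr, empty)
  expect_equal(rep0$enhancers$recall, 0)
  expect_true(is.na(rep0$enhancers$precision))
})

test_that("invalid designs are rejected", {
  expect_error(simulation_design(somatic_design = list(
    fractions = c(gain = 0.5, loss = 0.5, unaltered = 0.2, inactive = 0),
    gain_fold = 3, loss_fold = 1 / 3)), class = "se_validation_error")
  expect_error(simulation_design(somatic_design = list(
    fractions = c(gain = 0.25, loss = 0.25, unaltered = 0.25, inactive = 0.25),
    gain_fold = 1.5, loss_fold = 1 / 3)), class = "se_validation_error")
  expect_error(simulation_design(typical_width = c(-5, 100)),
               class = "se_validation_error")
  expect_error(simulation_design(not_a_field = 1), class = "se_validation_error")
})
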