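test_that("candidate calling finds maximal runs above threshold", {
  gm <- genome_model(c(chrT = 300), 50)
  sig <- list(chrT = c(0, 0, 5, 6, 7, 0))
  out <- call_candidate_regions(sig, gm, threshold = 4, min_width = 150)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(100, 250))
  # all below threshold -> empty
  expect_equal(nrow(call_candidate_regions(list(chrT = rep(1, 6)), gm, 4)), 0)
  # single above-threshold bin shorter than min_width -> dropped
  expect_equal(nrow(call_candidate_regions(list(chrT = c(0, 9, 0, 0, 0, 0)),
                                           gm, 4, min_width = 200)), 0)
})

test_that("candidate calling equals a run-length scan oracle", {
  gm <- tiny_genome(5e3)
  set.seed(8)
  for (k in 1:20) {
    sig <- round(runif(100, 0, 6), 2)
    out <- call_candidate_regions(list(chrT = sig), gm, threshold = 3,
                                  min_width = 100)
    # oracle: explicit scan
    above <- sig > 3
    runs <- list()
    i <- 1
    while (i <= 100) {
      if (above[i]) {
        j <- i
        while (j < 100 && above[j + 1]) j <- j + 1
        if ((j - i + 1) * 50 >= 100) {
          runs[[length(runs) + 1]] <- c((i - 1) * 50, j * 50)
        }
        i <- j + 1
      } else i <- i + 1
    }
    expect_equal(nrow(out), length(runs))
    if (length(runs)) {
      expect_equal(out$start, vapply(runs, `[`, 0, 1))
      expect_equal(out$end, vapply(runs, `[`, 0, 2))
    }
  }
})

test_that("distal filter uses min base-to-TSS distance with a 2.5 kb rule", {
  gm <- tiny_genome(1e5)
  tss <- data.frame(gene_id = "g1", chrom = "chrT", pos = 13499, strand = "+")
  agg3 <- track_from_bins(rep(1, 2000), gm, mark = "H3K4me3")
  agg1 <- track_from_bins(rep(10, 2000), gm, mark = "H3K4me1")
  keep <- filter_to_predicted_enhancers(regions("chrT", 10000, 11000), tss,
                                        agg3, agg1, gm)
  expect_equal(nrow(keep), 1) # distance exactly 2,500 -> kept
  expect_equal(keep$distance_to_tss, 2500)
  tss$pos <- 13400 # distance 2,401 -> excluded
  drop <- filter_to_predicted_enhancers(regions("chrT", 10000, 11000), tss,
                                        agg3, agg1, gm)
  expect_equal(nrow(drop), 0)
  # TSS inside the region -> distance 0
  expect_equal(distance_to_nearest_tss(regions("chrT", 10000, 11000),
                                       data.frame(chrom = "chrT", pos = 10500)), 0)
  expect_error(filter_to_predicted_enhancers(regions("chrT", 0, 1000),
                                             tss[0, ], agg3, agg1, gm),
               class = "se_validation_error")
})

test_that("H3K4me3/H3K4me1 ratio excludes promoter-like candidates", {
  gm <- tiny_genome(1e5)
  # H3K4me3 10 RPKM, H3K4me1 1 RPKM: log2(10.1/1.1) = 3.199 > 2.4 -> excluded
  agg3 <- track_from_bins(rep(5, 2000), gm, mark = "H3K4me3", library_size = 1e7)
  agg1 <- track_from_bins(rep(0.5, 2000), gm, mark = "H3K4me1", library_size = 1e7)
  tss <- data.frame(gene_id = "g1", chrom = "chrT", pos = 90000, strand = "+")
  cand <- regions("chrT", 10000, 11000)
  out <- filter_to_predicted_enhancers(cand, tss, agg3, agg1, gm)
  expect_equal(nrow(out), 0)
  ratio <- log2((10 + 0.1) / (1 + 0.1))
  expect_equal(ratio, 3.19878, tolerance = 1e-5)
})

test_that("distal and ratio filters commute", {
  gm <- tiny_genome(1e5)
  set.seed(12)
  tss <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "chrT",
                    pos = c(5000, 22000, 47000, 61000, 88000), strand = "+")
  agg3 <- nb_track(gm, mu = 2, mark = "H3K4me3")
  agg1 <- nb_track(gm, mu = 2, mark = "H3K4me1")
  cand <- random_regions_df(50, gm, max_width = 1500)
  both <- filter_to_predicted_enhancers(cand, tss, agg3, agg1, gm)
  # apply ratio first, then distal
  me3 <- compute_rpkm(agg3, cand, gm); me1 <- compute_rpkm(agg1, cand, gm)
  ratio_keep <- cand[log2((me3 + 0.1) / (me1 + 0.1)) <= 2.4, , drop = FALSE]
  other <- filter_to_predicted_enhancers(ratio_keep, tss, agg3, agg1, gm)
  expect_equal(sort(both$id), sort(other$id))
})

test_that("catalog merging matches the O(n^2) oracle and is idempotent", {
  a <- regions("chr1", 0, 100); b <- regions("chr1", 50, 150)
  m <- merge_catalog(list(A = a, B = b))
  expect_equal(c(m$start, m$end), c(0, 150))
  expect_equal(m$present_in, "A,B")
  m2 <- merge_catalog(list(A = regions("chr1", c(0, 200), c(100, 300))))
  expect_equal(nrow(m2), 2)
  # abutting intervals are not merged (>= 1 bp overlap required)
  ab <- merge_catalog(list(A = regions("chr1", 0, 100), B = regions("chr1", 100, 200)))
  expect_equal(nrow(ab), 2)
  set.seed(13)
  gm <- tiny_genome(2e4)
  for (k in 1:25) {
    sets <- list(A = random_regions_df(8, gm, 3000), B = random_regions_df(8, gm, 3000))
    got <- merge_catalog(sets)
    want <- oracle_merge(rbind(sets$A, sets$B))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    again <- merge_regions(got)
    expect_equal(again[, c("start", "end")], got[, c("start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("rank products multiply per-line ranks with average ties", {
  mat <- rbind(c(10, 9, 8), c(5, 10, 9), c(1, 1, 1))
  rp <- rank_product_recurrence(mat, n_perm = 100, seed = 1)
  expect_equal(rp$rank_product[1], 1 * 2 * 2)
  expect_equal(rp$rank_product[3], 3 * 3 * 3)
  # rank 1 in all lines is the minimum possible rank product
  best <- rank_product_recurrence(rbind(c(9, 9), c(1, 2), c(3, 1)), 100, seed = 1)
  expect_equal(best$rank_product[1], 1)
  expect_true(all(rp$p_empirical > 0 & rp$p_empirical <= 1))
  expect_error(rank_product_recurrence(mat, n_perm = 50),
               class = "se_validation_error")
  expect_error(rank_product_recurrence(mat[, 1, drop = FALSE], 100),
               class = "se_validation_error")
})

test_that("rank-product p-values are seeded and reproducible", {
  set.seed(20)
  mat <- matrix(rnorm(50 * 4), 50)
  a <- rank_product_recurrence(mat, n_perm = 300, seed = 5)
  b <- rank_product_recurrence(mat, n_perm = 300, seed = 5)
  expect_identical(a$p_empirical, b$p_empirical)
  expect_equal(a$is_recurrent, rowSums(mat > 0) >= 2)
})
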