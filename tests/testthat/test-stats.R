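test_that("snp enrichment reproduces the stated counts example", {
  # region set covering [0, 1000) of chr1; craft counts [[12,88],[1000,9000]]
  se <- regions("chr1", 0, 1000)
  trait <- data.frame(chrom = "chr1",
                      pos = c(seq(0, 999, length.out = 12),
                              seq(2000, 99000, length.out = 88)),
                      id = sprintf("s%03d", 1:100), trait = "t1")
  bg <- data.frame(chrom = "chr1",
                   pos = c(seq(0, 999, length.out = 1000),
                           seq(2000, 999000, length.out = 9000)),
                   id = sprintf("b%05d", 1:10000))
  res <- snp_enrichment(trait, bg, se)
  expect_equal(res$n_gwas_in, 12)
  expect_equal(res$enrichment_ratio, (12 / 88) / (1000 / 9000))
  tab <- matrix(c(12, 88, 1000, 9000), 2, byrow = TRUE)
  expect_equal(res$chi2_p, oracle_chisq_p(tab), tolerance = 1e-9)
})

test_that("null proportions give ratio 1 and traits under 10 hits are excluded", {
  se <- regions("chr1", 0, 1000)
  mk <- function(n_in, n_out, pre) {
    data.frame(chrom = "chr1",
               pos = c(seq(0, 999, length.out = n_in),
                       seq(5000, 99000, length.out = n_out)),
               id = sprintf("%s%04d", pre, seq_len(n_in + n_out)))
  }
  trait <- mk(10, 90, "t"); trait$trait <- "t1"
  bg <- mk(100, 900, "b")
  res <- snp_enrichment(trait, bg, se)
  expect_equal(res$enrichment_ratio, 1.0)
  expect_equal(stats::na.omit(res$chi2_p), 1, ignore_attr = TRUE) # statistic 0
  trait8 <- mk(8, 92, "t"); trait8$trait <- "t8"
  expect_message(res8 <- snp_enrichment(trait8, bg, se), "excluded")
  expect_equal(nrow(res8), 0)
  expect_error(snp_enrichment(trait, bg[0, ], se), class = "se_validation_error")
})

test_that("tf density counts sites by the 60% overlap rule", {
  # 30 qualifying summits over 0.25 Mbp -> 120 per Mbp
  reg <- regions("chr1", 0, 250000)
  summits <- regions("chr1", seq(100, by = 1000, length.out = 30),
                     seq(101, by = 1000, length.out = 30))
  expect_equal(tf_density(summits, reg)$density_per_mbp, 120)
  # 1,000-bp site with exactly 50% inside -> not counted
  site <- regions("chr1", 249500, 250500)
  expect_equal(tf_density(site, reg)$n_sites, 0L)
  # 60% inside is counted
  site6 <- regions("chr1", 249400, 250400)
  expect_equal(tf_density(site6, reg)$n_sites, 1L)
  expect_error(tf_density(site, reg[0, ]), class = "se_validation_error")
})

test_that("tf density matches an exhaustive overlap-fraction oracle", {
  set.seed(50)
  gm <- tiny_genome(5e4)
  for (k in 1:25) {
    reg <- merge_regions(random_regions_df(6, gm, 5000))
    sites <- random_regions_df(40, gm, 1500)
    got <- tf_density(sites, reg)
    want <- sum(vapply(seq_len(nrow(sites)), function(i) {
      oracle_overlap_bp(sites[i, ], reg) >= 0.6 * (sites$end[i] - sites$start[i])
    }, TRUE))
    expect_equal(got$n_sites, want)
    expect_equal(got$density_per_mbp, want / (sum(reg$end - reg$start) / 1e6))
  }
})

test_that("cooccupancy is the fraction of A summits near a B summit", {
  a <- regions("chr1", c(1000, 5000), c(1001, 5001))
  b <- regions("chr1", c(1300, 99000), c(1301, 99001))
  expect_equal(cooccupancy(a, b), 0.5)
  expect_equal(cooccupancy(a, a), 1.0)
  expect_equal(cooccupancy(a, b[0, ]), 0)
  expect_error(cooccupancy(a[0, ], b), class = "se_validation_error")
  set.seed(51)
  for (k in 1:25) {
    pa <- sample.int(2e5, 30); pb <- sample.int(2e5, 25)
    ca <- sample(c("c1", "c2"), 30, replace = TRUE)
    cb <- sample(c("c1", "c2"), 25, replace = TRUE)
    got <- cooccupancy(regions(ca, pa, pa + 1), regions(cb, pb, pb + 1),
                       window = 500)
    want <- mean(oracle_min_dist(pa, ca, pb, cb) <= 500)
    expect_equal(got, want)
  }
})

test_that("binned profiles are flat on uniform signal and conserve totals", {
  gm <- tiny_genome(1e5)
  flat <- track_from_bins(rep(4, 2000), gm)
  reg <- regions("chrT", 10000, 30000, id = "r1")
  prof <- binned_profile(flat, reg, gm, n_bins = 200)
  expect_equal(max(prof) - min(prof), 0)
  set.seed(52)
  bumpy <- nb_track(gm, mu = 3)
  reg2 <- regions("chrT", 1025, 3025, id = "r2") # 2,000 bp -> 10 bp slices
  prof2 <- binned_profile(bumpy, reg2, gm, n_bins = 200)
  total_from_slices <- sum(prof2[1, ] * 10) # RPKM x slice bp
  total_region <- compute_rpkm(bumpy, reg2, gm) * 2000
  expect_equal(total_from_slices, total_region, tolerance = 1e-6)
  expect_error(binned_profile(flat, regions("chrT", 0, 100), gm, 200),
               class = "se_validation_error")
})

test_that("depletion calls apply the percentile rule to WT - KD differences", {
  gm <- tiny_genome(2e5)
  set.seed(53)
  wt <- lapply(1:2, function(i) nb_track(gm, mu = 5, sample_id = paste0("wt", i)))
  kd <- nb_track(gm, mu = 5, sample_id = "kd")
  reg <- regions("chrT", 0, 2e5, id = "all")
  dc <- knockdown_depletion(wt, kd, reg, gm, subregion_width = 1000)
  expect_lt(dc$q1, dc$q99)
  expect_identical(dc$subregions$state,
                   ifelse(dc$subregions$diff > dc$q99, "depleted",
                          ifelse(dc$subregions$diff < dc$q1, "gained",
                                 "unchanged")))
  expect_error(knockdown_depletion(wt[1], kd, reg, gm),
               class = "se_validation_error")
})

test_that("planted knockdown depletion is detected and SE-biased", {
  gm <- tiny_genome(4e5)
  set.seed(54)
  base <- rnbinom(8000, mu = 10, size = 20)
  wt <- lapply(1:2, function(i)
    track_from_bins(base + rnbinom(8000, mu = 2, size = 20), gm,
                    sample_id = paste0("wt", i)))
  kd_counts <- base + rnbinom(8000, mu = 2, size = 20)
  kd_counts[1:4000] <- round(kd_counts[1:4000] * 0.3) # depleted in the SE region
  kd <- track_from_bins(kd_counts, gm, sample_id = "kd")
  reg <- regions("chrT", c(0, 2e5), c(2e5, 4e5), id = c("se", "typ"))
  dc <- knockdown_depletion(wt, kd, reg, gm, subregion_width = 1000,
                            region_class = c("super", "typical"))
  dep_rate_se <- mean(dc$subregions$state[dc$subregions$class == "super"] == "depleted")
  dep_rate_typ <- mean(dc$subregions$state[dc$subregions$class == "typical"] == "depleted")
  expect_gt(dep_rate_se, 0.9)
  expect_lt(dep_rate_typ, 0.1)
  expect_lt(dc$wilcox_p, 0.01)
})

test_that("target-downregulation permutation matches its binomial oracle", {
  set.seed(55)
  universe <- sprintf("g%04d", 1:2000)
  down <- setNames(runif(2000) < 0.10, universe)
  linked <- sample(universe, 8)
  down[linked] <- c(rep(TRUE, 6), rep(FALSE, 2))
  res <- target_downregulation_permutation(linked, down, n_perm = 10000, seed = 9)
  expect_equal(res$observed, 6)
  p_binom <- sum(dbinom(6:8, 8, mean(down)))
  expect_lt(abs(res$p_empirical - p_binom), 3 * sqrt(p_binom / 10000) + 1e-4)
  # saturated null: every gene down -> p = 1
  all_down <- setNames(rep(TRUE, 2000), universe)
  expect_equal(target_downregulation_permutation(linked, all_down, 200, 1)$p_empirical, 1)
  # observed 0 -> p = 1
  none <- down; none[linked] <- FALSE
  expect_equal(target_downregulation_permutation(linked, none, 200, 1)$p_empirical, 1)
  expect_error(target_downregulation_permutation(character(0), down, 200),
               class = "se_validation_error")
})

test_that("conservation score is the window maximum around the midpoint", {
  gm <- tiny_genome(1e5)
  const <- list(chrT = rep(0.3, 2000))
  reg <- regions("chrT", 10000, 12000) # midpoint 11,000
  expect_equal(conservation_max(reg, const, gm), 0.3)
  spike <- list(chrT = rep(0.1, 2000))
  spike$chrT[ceiling(11400 / 50)] <- 0.9 # inside [10500, 11500]
  expect_equal(conservation_max(reg, spike, gm), 0.9)
  nacov <- list(chrT = rep(NA_real_, 2000))
  expect_true(is.na(conservation_max(reg, nacov, gm)))
  set.seed(56)
  sc <- list(chrT = runif(2000))
  for (k in 1:20) {
    start <- sample.int(9e4, 1)
    r <- regions("chrT", start, start + 2000)
    midpoint <- floor((2 * start + 2000) / 2)
    lo <- max(midpoint - 500, 0); hi <- min(midpoint + 500, 1e5)
    want <- max(sc$chrT[(lo %/% 50 + 1):ceiling(hi / 50)])
    expect_equal(conservation_max(r, sc, gm), want)
  }
})
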