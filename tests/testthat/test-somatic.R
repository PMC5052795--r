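test_that("pair-level gain/loss rules follow the printed thresholds", {
  # T=2.0, N=0.9: fold (2.1/1.0)=2.1 >= 2 and diff 1.1 > 0.5 -> gain pair
  tum <- matrix(c(2.0, 2.5, 0.1, 0.1), 1)
  nrm <- matrix(c(0.9, 1.0, 2.0, 2.2), 1)
  sc <- classify_somatic(tum, nrm)
  expect_equal(sc$calls$n_gain_pairs, 2L)
  expect_equal(sc$calls$n_loss_pairs, 2L)
  # fold 1.3 in all pairs with healthy signal -> unaltered
  tum2 <- matrix(rep(1.2, 4), 1); nrm2 <- matrix(rep(0.9, 4), 1)
  expect_equal(classify_somatic(tum2, nrm2)$calls$class, "unaltered")
  # max primary RPKM below 0.5 -> inactive regardless of folds
  tum3 <- matrix(c(0.4, 0.4, 0.01, 0.01), 1)
  nrm3 <- matrix(c(0.05, 0.05, 0.3, 0.3), 1)
  expect_equal(classify_somatic(tum3, nrm3)$calls$class, "inactive")
  expect_error(classify_somatic(matrix(1, 1, 2), matrix(c(1, NA), 1)),
               class = "se_pairing_error")
})

test_that("every SE gets exactly one class and counts sum to catalog size", {
  set.seed(30)
  n <- 200
  tum <- matrix(rexp(n * 4, 0.2), n)
  nrm <- matrix(rexp(n * 4, 0.2), n)
  sc <- suppressMessages(classify_somatic(tum, nrm))
  expect_equal(nrow(sc$calls), n)
  expect_true(all(sc$calls$class %in% c("gain", "loss", "unaltered", "inactive")))
  expect_equal(sum(table(sc$calls$class)), n)
})

test_that("swapping tumour and normal maps gain to loss and back", {
  set.seed(31)
  n <- 300
  tum <- matrix(rexp(n * 6, 0.2), n)
  nrm <- matrix(rexp(n * 6, 0.2), n)
  fwd <- suppressMessages(classify_somatic(tum, nrm))
  rev <- suppressMessages(classify_somatic(nrm, tum))
  no_tie <- !(fwd$calls$n_gain_pairs >= 2 & fwd$calls$n_loss_pairs >= 2 &
                fwd$calls$n_gain_pairs == fwd$calls$n_loss_pairs)
  mapped <- c(gain = "loss", loss = "gain",
              unaltered = "unaltered", inactive = "inactive")
  expect_identical(rev$calls$class[no_tie],
                   unname(mapped[fwd$calls$class[no_tie]]))
  expect_identical(rev$calls$n_gain_pairs, fwd$calls$n_loss_pairs)
})

test_that("methylation deltas average probes in the region", {
  se <- regions("chr1", 1000, 3000, id = "SE_1")
  probes <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                       pos = c(1500, 2500, 90000))
  beta <- matrix(c(0.2, 0.4, 0.9, 0.5, 0.7, 0.9), 3,
                 dimnames = list(c("p1", "p2", "p3"), c("T_P01", "N_P01")))
  pairs <- data.frame(tumor = "T_P01", normal = "N_P01")
  md <- methylation_delta(se, probes, beta, pairs)
  expect_equal(unname(md$delta[1, 1]), -0.3) # mean(0.2,0.4) - mean(0.5,0.7)
  # identical tables -> all deltas zero
  beta0 <- beta; beta0[, 1] <- beta0[, 2]
  md0 <- methylation_delta(se, probes, beta0, pairs)
  expect_equal(unname(md0$delta[1, 1]), 0)
  # region with no probes -> NA
  md_na <- methylation_delta(regions("chr1", 5e4, 6e4, id = "SE_2"),
                             probes, beta, pairs)
  expect_true(is.na(md_na$delta[1, 1]))
})

test_that("planted methylation coupling yields a significant one-sided test", {
  set.seed(32)
  n_se <- 50
  se <- regions("chr1", seq(0, by = 10000, length.out = 2 * n_se),
                seq(2000, by = 10000, length.out = 2 * n_se),
                id = sprintf("SE_%03d", 1:(2 * n_se)))
  probes <- data.frame(probe_id = sprintf("p%03d", 1:(2 * n_se)),
                       chrom = "chr1", pos = se$start + 500)
  classes <- rep(c("gain", "loss"), each = n_se)
  delta <- ifelse(classes == "gain", rnorm(2 * n_se, -0.2, 0.05),
                  rnorm(2 * n_se, 0.2, 0.05))
  beta <- cbind(T_P01 = 0.5 + delta, N_P01 = 0.5)
  rownames(beta) <- probes$probe_id
  md <- methylation_delta(se, probes, beta,
                          data.frame(tumor = "T_P01", normal = "N_P01"), classes)
  expect_lt(md$p_value, 0.01)
})

test_that("expression fold/difference rules and lfc match the stated examples", {
  links <- data.frame(se_id = c("SE_1", "SE_2"), gene_id = c("g1", "g2"))
  fpkm <- matrix(c(4.0, 0.8, 1.0, 0.5), 2,
                 dimnames = list(c("g1", "g2"), c("T_P01", "N_P01")))
  pairs <- data.frame(tumor = "T_P01", normal = "N_P01")
  ea <- expression_association(links, fpkm, pairs)
  expect_equal(unname(ea$lfc["SE_1", 1]), log2(4.1 / 1.1))
  expect_true(ea$differential["SE_1", 1])   # fold 4, diff 3
  expect_false(ea$differential["SE_2", 1])  # fold 1.6
  # unlinked rows are skipped with a message
  links2 <- rbind(links, data.frame(se_id = "SE_3", gene_id = "missing"))
  expect_message(expression_association(links2, fpkm, pairs), "skipping")
})

test_that("cnv overlay takes length-weighted means against fixed thresholds", {
  se <- regions("chr1", c(0, 0, 0), c(1000, 1000, 1000),
                id = c("a", "b", "c"))
  expect_equal(suppressMessages(cnv_overlay(
    regions("chr1", 0, 1000, id = "a"),
    data.frame(chrom = "chr1", start = 0, end = 1000, log_ratio = 0.8)))$status,
    "gain")
  expect_equal(suppressMessages(cnv_overlay(
    regions("chr1", 0, 1000, id = "a"),
    data.frame(chrom = "chr1", start = 0, end = 1000, log_ratio = -1.2)))$status,
    "loss")
  # 60% at 0.0 and 40% at 1.0 -> weighted mean 0.4 -> neutral
  two <- data.frame(chrom = "chr1", start = c(0, 600), end = c(600, 1000),
                    log_ratio = c(0, 1))
  res <- suppressMessages(cnv_overlay(regions("chr1", 0, 1000, id = "a"), two))
  expect_equal(res$mean_log_ratio, 0.4)
  expect_equal(res$status, "neutral")
  overl <- data.frame(chrom = "chr1", start = c(0, 500), end = c(600, 1000),
                      log_ratio = c(0, 1))
  expect_error(cnv_overlay(regions("chr1", 0, 1000, id = "a"), overl),
               class = "se_validation_error")
  # no overlapping segment -> neutral with NA ratio
  far <- data.frame(chrom = "chr2", start = 0, end = 1000, log_ratio = 2)
  res2 <- suppressMessages(cnv_overlay(regions("chr1", 0, 1000, id = "a"), far))
  expect_true(is.na(res2$mean_log_ratio))
  expect_equal(res2$status, "neutral")
})
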