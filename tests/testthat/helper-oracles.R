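# Brute-force oracles, kept deliberately independent of the package's
# vectorized implementations, plus small fixture builders.

# Reads in [start, end) by looping over genome bins and prorating overlap.
oracle_region_reads <- function(bins, start, end, bin_size) {
  total <- 0
  for (b in seq_along(bins)) {
    b0 <- (b - 1) * bin_size
    b1 <- b * bin_size
    ov <- max(0, min(end, b1) - max(start, b0))
    total <- total + bins[b] * ov / bin_size
  }
  total
}

# Transitive merging of intervals overlapping by >= 1 bp: O(n^2) fixpoint.
oracle_merge <- function(df) {
  rows <- split(df[, c("chrom", "start", "end")], seq_len(nrow(df)))
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < length(rows)) {
      j <- i + 1
      while (j <= length(rows)) {
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          rows[[i]]$start <- min(a$start, b$start)
          rows[[i]]$end <- max(a$end, b$end)
          rows[[j]] <- NULL
          merged_any <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Union-find stitching: chain intervals whose gap is <= gap.
oracle_stitch <- function(df, gap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && df$chrom[i] == df$chrom[j]) {
      g <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
      if (g <= gap) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    m <- df[comp == k, , drop = FALSE]
    data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Exhaustive nearest-TSS scan for one point; tie -> smaller coordinate.
oracle_nearest_tss <- function(center, chrom, tss) {
  cand <- tss[tss$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  d <- abs(cand$pos - center)
  hit <- cand[d == min(d), , drop = FALSE]
  hit[order(hit$pos), ][1, ]
}

# Exhaustive hockey-stick argmax of x - y over all indices.
oracle_cutoff_index <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- (i - 1) / (n - 1) - (s[i] - s[1]) / (s[n] - s[1])
  }
  max(which(d >= max(d) - 1e-12))
}

# Per-site overlap fraction with a region set, by direct looping.
oracle_overlap_bp <- function(site, reg) {
  tot <- 0
  for (r in seq_len(nrow(reg))) {
    if (reg$chrom[r] == site$chrom) {
      tot <- tot + max(0, min(site$end, reg$end[r]) - max(site$start, reg$start[r]))
    }
  }
  tot
}

# All-pairs minimum summit distance.
oracle_min_dist <- function(pos_a, chrom_a, pos_b, chrom_b) {
  vapply(seq_along(pos_a), function(i) {
    d <- abs(pos_b[chrom_b == chrom_a[i]] - pos_a[i])
    if (length(d) == 0) Inf else min(d)
  }, 0)
}

# One-sided hypergeometric upper-tail sum via choose(), independent of
# fisher.test / phyper.
oracle_hyper_upper <- function(a, b, cc, d) {
  m <- a + b          # query genes
  k <- a + cc         # set size
  N <- a + b + cc + d
  ks <- a:min(m, k)
  sum(exp(lchoose(k, ks) + lchoose(N - k, m - ks) - lchoose(N, m)))
}

# 2x2 chi-square statistic and p from the textbook formula.
oracle_chisq_p <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Fixture builders ----------------------------------------------------------

tiny_genome <- function(len = 1e5, bin = 50) {
  genome_model(c(chrT = len), bin)
}

# Track from an explicit per-bin count vector on a one-chromosome genome.
track_from_bins <- function(counts, genome, sample_id = "s1", mark = "H3K27ac",
                            library_size = 1e7) {
  chrom <- names(genome$chroms)[1]
  nb <- ceiling(genome$chroms[[chrom]] / genome$bin_size)
  stopifnot(length(counts) == nb)
  signal_track(sample_id, mark, library_size,
               stats::setNames(list(counts), chrom), genome)
}

# Flat negative-binomial background track.
nb_track <- function(genome, mu = 1, size = 10, library_size = 1e7,
                     sample_id = "s1", mark = "H3K27ac") {
  bins <- lapply(n_bins_of(genome), function(n) stats::rnbinom(n, mu = mu, size = size))
  signal_track(sample_id, mark, library_size, bins, genome)
}

n_bins_of <- function(genome) {
  stats::setNames(as.integer(ceiling(genome$chroms / genome$bin_size)),
                  names(genome$chroms))
}

random_regions_df <- function(n, genome, max_width = 2000) {
  chrom <- sample(names(genome$chroms), n, replace = TRUE)
  w <- sample(50:max_width, n, replace = TRUE)
  start <- floor(runif(n, 0, genome$chroms[chrom] - w))
  regions(chrom, start, start + w, genome = genome)
}

small_design <- function(...) {
  simulation_design(chrom_lengths = c(chr1 = 3e6, chr2 = 3e6), n_genes = 80,
                    n_enhancer_clusters = 30, n_cell_lines = 3, n_pairs = 4,
                    n_background_snps = 4000, n_trait_snps = 400, ...)
}
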