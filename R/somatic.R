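#' Somatic classification of super-enhancers against matched pairs
#'
#' Per tumour/normal pair, a pair supports gain when the H3K27ac fold change
#' `(T + c)/(N + c)` is >= `fold_thresh` and the absolute difference `T - N`
#' exceeds `diff_thresh`; loss is the mirror image (fold <= 1/fold_thresh,
#' difference < -diff_thresh). Classes are assigned in order: *inactive*
#' when the maximum corrected RPKM over all primary samples (tumours and
#' normals) is below `inactive_rpkm`; *gain* when gain pairs reach
#' `min_recurrent_pairs` and are not outnumbered by loss pairs; *loss* when
#' loss pairs reach `min_recurrent_pairs`; else *unaltered*. When both gain
#' and loss are recurrent the class with more supporting pairs wins (tie:
#' gain) and the conflict is recorded.
#'
#' @param tumor_mat,normal_mat Numeric matrices, super-enhancers x pairs, of
#'   input-corrected H3K27ac RPKM; identical dimnames.
#' @param min_recurrent_pairs Pairs required for a recurrent call (default 2).
#' @param fold_thresh Fold threshold (default 2).
#' @param diff_thresh Absolute RPKM difference threshold (default 0.5).
#' @param inactive_rpkm Activity floor for primary samples (default 0.5).
#' @param pseudocount Pseudocount on both fold terms (default 0.1).
#' @return List of class `somatic_calls`: `calls` data.frame (se_id, class,
#'   n_gain_pairs, n_loss_pairs, max_primary_rpkm, conflict), `fold` and
#'   `diff` matrices.
#' @export
classify_somatic <- function(tumor_mat, normal_mat, min_recurrent_pairs = 2L,
                             fold_thresh = 2, diff_thresh = 0.5,
                             inactive_rpkm = 0.5, pseudocount = 0.1) {
  if (is.null(dim(tumor_mat)) || !identical(dim(tumor_mat), dim(normal_mat))) {
    stop_se("tumor and normal matrices must have identical dimensions",
            "se_pairing_error")
  }
  if (ncol(tumor_mat) < 2) stop_se("need >= 2 tumor/normal pairs", "se_validation_error")
  if (anyNA(tumor_mat) || anyNA(normal_mat)) {
    stop_se("missing pair member (NA signal)", "se_pairing_error")
  }
  fold <- (tumor_mat + pseudocount) / (normal_mat + pseudocount)
  diff <- tumor_mat - normal_mat
  gain_pair <- fold >= fold_thresh & diff > diff_thresh
  loss_pair <- fold <= 1 / fold_thresh & diff < -diff_thresh
  n_gain <- rowSums(gain_pair)
  n_loss <- rowSums(loss_pair)
  max_primary <- pmax(apply(tumor_mat, 1, max), apply(normal_mat, 1, max))
  cls <- rep("unaltered", nrow(tumor_mat))
  gain_rec <- n_gain >= min_recurrent_pairs
  loss_rec <- n_loss >= min_recurrent_pairs
  cls[loss_rec] <- "loss"
  cls[gain_rec & n_gain >= n_loss] <- "gain"
  conflict <- gain_rec & loss_rec
  cls[max_primary < inactive_rpkm] <- "inactive"
  if (any(conflict)) {
    message(sprintf("%d super-enhancer(s) with both recurrent gain and loss evidence; class set by pair majority (tie: gain)",
                    sum(conflict)))
  }
  ids <- rownames(tumor_mat)
  if (is.null(ids)) ids <- sprintf("SE_%05d", seq_len(nrow(tumor_mat)))
  structure(list(
    calls = data.frame(se_id = ids, class = cls,
                       n_gain_pairs = as.integer(n_gain),
                       n_loss_pairs = as.integer(n_loss),
                       max_primary_rpkm = max_primary,
                       conflict = conflict,
                       stringsAsFactors = FALSE),
    fold = fold, diff = diff), class = "somatic_calls")
}

#' @export
print.somatic_calls <- function(x, ...) {
  tab <- table(factor(x$calls$class, c("gain", "loss", "unaltered", "inactive")))
  cat("somatic_calls:", nrow(x$calls), "super-enhancers\n")
  print(tab)
  cat(sprintf("  (%s)\n", paste(sprintf("%s %.0f%%", names(tab),
                                        100 * tab / sum(tab)), collapse = ", ")))
  invisible(x)
}

#' Differential methylation over super-enhancers
#'
#' Per super-enhancer and pair, the beta difference is the mean tumour beta
#' minus the mean normal beta over probes falling in the region (NA when no
#' probe falls inside). The class-level comparison is a one-sided Welch
#' t-test that gain-class differences are lower than loss-class differences.
#'
#' @param se_regions Super-enhancer region data.frame (ids in `id`).
#' @param probes data.frame with `probe_id`, `chrom`, `pos` (0-based).
#' @param beta Numeric matrix probes x samples (rownames = probe_id).
#' @param pairs data.frame with `tumor`, `normal` sample-column names.
#' @param classes Character vector of somatic classes aligned to `se_regions`.
#' @return List: `delta` (SE x pair matrix), `mean_delta` per SE, `p_value`
#'   of the gain-vs-loss test (NA when either class has no data).
#' @export
methylation_delta <- function(se_regions, probes, beta, pairs, classes = NULL) {
  delta <- matrix(NA_real_, nrow(se_regions), nrow(pairs),
                  dimnames = list(se_regions$id, pairs$tumor))
  for (i in seq_len(nrow(se_regions))) {
    in_se <- probes$chrom == se_regions$chrom[i] &
      probes$pos >= se_regions$start[i] & probes$pos < se_regions$end[i]
    if (!any(in_se)) next
    pr <- probes$probe_id[in_se]
    bt <- beta[pr, pairs$tumor, drop = FALSE]
    bn <- beta[pr, pairs$normal, drop = FALSE]
    delta[i, ] <- colMeans(bt) - colMeans(bn)
  }
  mean_delta <- rowMeans(delta)
  p <- NA_real_
  if (!is.null(classes)) {
    g <- mean_delta[classes == "gain"]; l <- mean_delta[classes == "loss"]
    g <- g[is.finite(g)]; l <- l[is.finite(l)]
    if (length(g) >= 2 && length(l) >= 2) {
      p <- stats::t.test(g, l, alternative = "less")$p.value
    }
  }
  list(delta = delta, mean_delta = mean_delta, p_value = p)
}

#' Expression association of linked genes
#'
#' Per linked gene and pair: log2 fold change `log2((T + 0.1)/(N + 0.1))`,
#' and a differential flag when the raw fold change is >= 2 and the absolute
#' FPKM difference is >= 0.5. The class-level comparison is a one-sided
#' Welch t-test that gain-class log fold changes exceed unaltered-class ones.
#'
#' @param links data.frame with `se_id`, `gene_id` (unlinked rows dropped
#'   with a message).
#' @param fpkm Numeric matrix genes x samples (rownames = gene_id).
#' @param pairs data.frame with `tumor`, `normal` column names.
#' @param classes Named character vector of classes indexed by se_id.
#' @param pseudocount Pseudocount for the log fold change (default 0.1).
#' @return List: `lfc` (links x pairs), `mean_lfc`, `differential` logical
#'   matrix, `p_value` gain-vs-unaltered.
#' @export
expression_association <- function(links, fpkm, pairs, classes = NULL,
                                   pseudocount = 0.1) {
  ok <- !is.na(links$gene_id) & links$gene_id %in% rownames(fpkm)
  if (any(!ok)) {
    message(sprintf("skipping %d unlinked super-enhancer(s)", sum(!ok)))
  }
  lk <- links[ok, , drop = FALSE]
  Tm <- fpkm[lk$gene_id, pairs$tumor, drop = FALSE]
  Nm <- fpkm[lk$gene_id, pairs$normal, drop = FALSE]
  lfc <- log2((Tm + pseudocount) / (Nm + pseudocount))
  raw_fold <- ifelse(pmin(Tm, Nm) == 0,
                     ifelse(pmax(Tm, Nm) == 0, 1, Inf),
                     pmax(Tm, Nm) / pmin(Tm, Nm))
  differential <- raw_fold >= 2 & abs(Tm - Nm) >= 0.5
  rownames(lfc) <- rownames(differential) <- lk$se_id
  mean_lfc <- rowMeans(lfc)
  p <- NA_real_
  if (!is.null(classes)) {
    cl <- classes[lk$se_id]
    g <- mean_lfc[cl == "gain"]; u <- mean_lfc[cl == "unaltered"]
    if (sum(is.finite(g)) >= 2 && sum(is.finite(u)) >= 2) {
      p <- stats::t.test(g, u, alternative = "greater")$p.value
    }
  }
  list(lfc = lfc, mean_lfc = mean_lfc, differential = differential, p_value = p)
}

#' Copy-number status of a super-enhancer
#'
#' Length-weighted mean log ratio over the copy-number segments overlapping
#' each region; status gain when > `gain_thr`, loss when < `loss_thr`, else
#' neutral. Regions without any overlapping segment are neutral (log ratio
#' NA).
#'
#' @param se_regions Region data.frame.
#' @param segments data.frame `chrom`, `start`, `end`, `log_ratio`
#'   (non-overlapping).
#' @param gain_thr,loss_thr Log-ratio thresholds (defaults 0.6 and -1.0).
#' @return data.frame: se_id, mean_log_ratio, status.
#' @export
cnv_overlay <- function(se_regions, segments, gain_thr = 0.6, loss_thr = -1.0) {
  seg <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop_se("copy-number segments overlap", "se_validation_error")
    }
  }
  mean_lr <- rep(NA_real_, nrow(se_regions))
  for (i in seq_len(nrow(se_regions))) {
    s <- seg[seg$chrom == se_regions$chrom[i], , drop = FALSE]
    ov <- pmin(s$end, se_regions$end[i]) - pmax(s$start, se_regions$start[i])
    keep <- ov > 0
    if (any(keep)) {
      mean_lr[i] <- sum(s$log_ratio[keep] * ov[keep]) / sum(ov[keep])
    }
  }
  status <- rep("neutral", nrow(se_regions))
  status[!is.na(mean_lr) & mean_lr > gain_thr] <- "gain"
  status[!is.na(mean_lr) & mean_lr < loss_thr] <- "loss"
  if (anyNA(mean_lr)) {
    message(sprintf("%d region(s) without copy-number coverage set to neutral",
                    sum(is.na(mean_lr))))
  }
  data.frame(se_id = se_regions$id, mean_log_ratio = mean_lr, status = status,
             stringsAsFactors = FALSE)
}
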