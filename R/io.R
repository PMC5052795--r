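#' @import data.table
NULL

# All on-disk interval formats are BED-style 0-based half-open. SNP catalogs
# are the one 1-based source format; positions are converted to 0-based on
# read and back on write.

#' Read a bedGraph of binned counts into a signal track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#'   Bins absent from the file are zero.
#' @param genome A `genome_model`; every line must sit on the genome bin grid.
#' @param sample_id,mark,library_size Track metadata.
#' @return A `signal_track`.
#' @export
read_bedgraph_track <- function(path, genome, sample_id, mark, library_size) {
  if (!file.exists(path)) stop_se(paste("no such file:", path), "se_io_error")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  bs <- genome$bin_size
  if (nrow(dt) > 0) {
    if (any(dt$start %% bs != 0) || any((dt$end %% bs != 0) & (dt$end != genome$chroms[dt$chrom]))) {
      stop_se(sprintf("%s: bedGraph intervals not aligned to the %d bp bin grid",
                      basename(path), bs), "se_format_error")
    }
    if (any(!dt$chrom %in% names(genome$chroms)) ||
        any(dt$end > genome$chroms[dt$chrom]) || any(dt$start < 0)) {
      stop_se(sprintf("%s: coordinates out of genome bounds", basename(path)),
              "se_validation_error")
    }
  }
  nb <- n_bins(genome)
  bins <- lapply(nb, numeric)
  dtdf <- as.data.frame(dt)
  for (cm in unique(dtdf$chrom)) {
    d <- dtdf[dtdf$chrom == cm, , drop = FALSE]
    v <- bins[[cm]]
    i0 <- d$start %/% bs + 1
    i1 <- ceiling(d$end / bs)
    if (any(i1 > i0)) { # run-length compressed lines span several bins
      for (j in which(i1 > i0)) v[i0[j]:i1[j]] <- d$value[j]
      one <- which(i1 == i0)
      v[i0[one]] <- d$value[one]
    } else {
      v[i0] <- d$value
    }
    bins[[cm]] <- v
  }
  signal_track(sample_id, mark, library_size, bins, genome)
}

#' Write a signal track as bedGraph
#'
#' Consecutive equal-valued bins are run-length merged; zero bins are omitted
#' (bedGraph semantics: absent means 0). Read-back through
#' [read_bedgraph_track()] reproduces the bin vectors exactly.
#'
#' @param track A `signal_track`.
#' @param genome A `genome_model`.
#' @param path Output file.
#' @export
write_bedgraph_track <- function(track, genome, path) {
  bs <- genome$bin_size
  parts <- vector("list", length(track$bins))
  for (k in seq_along(track$bins)) {
    chrom <- names(track$bins)[k]
    v <- track$bins[[chrom]]
    r <- rle(v)
    end_bin <- cumsum(r$lengths)
    start_bin <- end_bin - r$lengths
    keep <- r$values != 0
    parts[[k]] <- data.table::data.table(
      chrom = chrom,
      start = start_bin[keep] * bs,
      end = pmin(end_bin[keep] * bs, genome$chroms[[chrom]]),
      value = r$values[keep])
  }
  dt <- data.table::rbindlist(parts)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 12)
  invisible(path)
}

#' Read/write BED interval files
#'
#' BED3 plus an optional 4th name column; 0-based half-open, written back
#' unchanged (round-trip identity).
#'
#' @param path File path.
#' @param genome Optional `genome_model` for bounds validation.
#' @return Region data.frame.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop_se(paste("no such file:", path), "se_io_error")
  if (file.size(path) == 0) return(regions(character(0), numeric(0), numeric(0)))
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  id <- if (ncol(dt) >= 4) as.character(dt[[4]]) else NULL
  regions(dt[[1]], dt[[2]], dt[[3]], id = id, genome = genome)
}

#' @rdname read_bed
#' @param reg Region data.frame.
#' @export
write_bed <- function(reg, path) {
  dt <- data.table::as.data.table(reg[, c("chrom", "start", "end", "id")])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 12)
  invisible(path)
}

#' @keywords internal
read_tsv_ <- function(path) {
  if (!file.exists(path)) stop_se(paste("no such file:", path), "se_io_error")
  as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
}

#' @keywords internal
write_tsv_ <- function(df, path) {
  data.table::fwrite(data.table::as.data.table(df), path, sep = "\t", scipen = 12)
  invisible(path)
}

#' Load a dataset directory
#'
#' Reads the declarative layout written by [write_dataset()] /
#' `generate_dataset()`: `config.json` (genome, bin size, thresholds),
#' `manifest.tsv` (sample_id, patient, role, mark, library_size, path),
#' per-track bedGraphs, `tss.tsv`, and the optional tables (`fpkm.tsv`,
#' `beta.tsv`, `snps.tsv`, `snps_background.tsv`, `cnv.tsv`, `genesets.tsv`,
#' `tf_*.bed`). Validates bin alignment, coordinate bounds and tumour/normal
#' pairing.
#'
#' @param dir Dataset directory.
#' @return A list (class `se_dataset`) with genome, manifest, tracks (named
#'   `sample|mark`), tss, and whatever optional tables are present.
#' @export
load_dataset <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop_se("config.json missing", "se_io_error")
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  genome <- genome_model(stats::setNames(as.numeric(cfg$genome$length),
                                         cfg$genome$chrom),
                         cfg$bin_size)
  manifest <- read_tsv_(file.path(dir, "manifest.tsv"))
  req <- c("sample_id", "patient", "role", "mark", "library_size", "path")
  if (!all(req %in% names(manifest))) {
    stop_se("manifest.tsv missing required columns", "se_format_error")
  }
  # tumour/normal pairing: every tumour patient needs a normal H3K27ac+input
  prim <- manifest[manifest$role %in% c("tumor", "normal"), ]
  for (p in unique(prim$patient)) {
    roles <- unique(prim$role[prim$patient == p])
    if (!all(c("tumor", "normal") %in% roles)) {
      stop_se(sprintf("patient %s lacks a matched %s sample", p,
                      setdiff(c("tumor", "normal"), roles)[1]),
              "se_pairing_error")
    }
  }
  tracks <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    tracks[[paste(m$sample_id, m$mark, sep = "|")]] <-
      read_bedgraph_track(file.path(dir, m$path), genome, m$sample_id, m$mark,
                          m$library_size)
  }
  ds <- list(genome = genome, config = cfg, manifest = manifest,
             tracks = tracks,
             tss = read_tsv_(file.path(dir, "tss.tsv")))
  opt <- c(fpkm = "fpkm.tsv", beta = "beta.tsv", snps = "snps.tsv",
           snps_background = "snps_background.tsv", cnv = "cnv.tsv",
           genesets = "genesets.tsv")
  for (nm in names(opt)) {
    p <- file.path(dir, opt[[nm]])
    if (file.exists(p)) ds[[nm]] <- read_tsv_(p)
  }
  # SNP positions are 1-based on disk; convert to 0-based internally
  for (nm in c("snps", "snps_background")) {
    if (!is.null(ds[[nm]])) ds[[nm]]$pos <- ds[[nm]]$pos - 1
  }
  tf_files <- list.files(dir, pattern = "^tf_.*\\.bed$", full.names = TRUE)
  if (length(tf_files)) {
    ds$tf_summits <- stats::setNames(
      lapply(tf_files, read_bed, genome = genome),
      sub("^tf_(.*)\\.bed$", "\\1", basename(tf_files)))
  }
  message(sprintf("loaded dataset: %d tracks, %d samples (%d cell lines, %d pairs), %d TSS",
                  length(tracks), length(unique(manifest$sample_id)),
                  sum(manifest$role == "cell_line" & manifest$mark == "H3K27ac"),
                  length(unique(manifest$patient[manifest$role == "tumor"])),
                  nrow(ds$tss)))
  class(ds) <- "se_dataset"
  ds
}

#' Write pipeline results to disk
#'
#' BED files for region catalogs and headered tab-separated tables for calls
#' and statistics, with fixed deterministic column orders. The somatic-call
#' table columns are `se_id, class, n_gain_pairs, n_loss_pairs,
#' max_primary_rpkm`.
#'
#' @param results Pipeline result list (see [run_pipeline()]); any subset of
#'   the recognized components is written.
#' @param out_dir Output directory, created if needed.
#' @return Invisible character vector of written paths.
#' @export
write_results <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_se(paste("cannot create", out_dir), "se_io_error")
  written <- character(0)
  emit_bed <- function(reg, name) {
    p <- file.path(out_dir, name)
    write_bed(reg, p)
    written <<- c(written, p)
  }
  emit_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$enhancers)) {
    emit_bed(results$enhancers[, c("chrom", "start", "end", "id")], "predicted_enhancers.bed")
    emit_tsv(results$enhancers, "predicted_enhancers.tsv")
  }
  if (!is.null(results$se_catalog)) {
    emit_bed(results$se_catalog[, c("chrom", "start", "end", "id")], "super_enhancers.bed")
    emit_tsv(results$se_catalog, "super_enhancers.tsv")
  }
  if (!is.null(results$typical_catalog)) {
    emit_bed(results$typical_catalog[, c("chrom", "start", "end", "id")], "typical_enhancers.bed")
  }
  if (!is.null(results$somatic)) {
    emit_tsv(results$somatic$calls[, c("se_id", "class", "n_gain_pairs",
                                       "n_loss_pairs", "max_primary_rpkm")],
             "somatic_calls.tsv")
  }
  if (!is.null(results$recurrence)) emit_tsv(results$recurrence, "recurrence.tsv")
  if (!is.null(results$links)) emit_tsv(results$links, "gene_links.tsv")
  if (!is.null(results$snp_enrichment)) emit_tsv(results$snp_enrichment, "snp_enrichment.tsv")
  if (!is.null(results$qc)) emit_tsv(results$qc, "qc.tsv")
  invisible(written)
}
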