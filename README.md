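# somaSE

Somatic super-enhancer analysis of tumour cohorts from fixed-bin (50 bp)
histone-mark signal tracks.

Super-enhancers — clusters of enhancers with exceptionally high H3K27ac —
are reshaped in cancer: relative to matched normal tissue, a tumour may
*gain* a super-enhancer, *lose* one, leave it *unaltered*, or the region
may be *inactive* in primary tissue altogether. somaSE is a tested,
reusable R implementation of the full analysis chain for this question, for
epigenomics researchers who have binned ChIP-seq signal (bedGraph), a TSS
table, and the usual companion tables (FPKM, methylation betas, SNP
catalogs, TF summits, CNV segments):

1. **Quantification** — region RPKM
   (`reads x 1e9 / (library_size x width)`) from binned counts with
   fractional-bin proration, input correction by floored subtraction, and
   empirical background models from 100,000 random regions (presence =
   corrected RPKM above the background 99th percentile, an empirical
   P < 0.01 test).
2. **Predicted enhancers** — threshold run-length candidate calling, a
   2.5-kb distal filter against all TSSs, and exclusion of promoter-like
   regions with aggregate H3K4me3/H3K4me1 log2 ratio > 2.4.
3. **Super-enhancers** — ROSE-style stitching of enhancers within 12.5 kb
   and the hockey-stick cutoff: signals sorted ascending and rescaled to
   the unit square, cutoff at the slope-1 tangent point `argmax(x - y)`,
   super iff strictly above the cutoff signal; per-line catalogs merged at
   ≥ 1 bp overlap. Recurrence across lines by rank products with a
   10,000-permutation null.
4. **Somatic classification** — per tumour/normal pair, gain = fold ≥ 2 and
   difference > 0.5 RPKM (loss mirror-image); class inactive when no
   primary sample reaches 0.5 RPKM, else gain / loss with ≥ 2 recurrent
   pairs, else unaltered.
5. **Gene assignment** — active promoters (TSS ± 500 bp above background)
   and nearest-active-TSS links from the super-enhancer centre.
6. **Integration statistics** — GWAS SNP enrichment vs a background SNP
   catalog (chi-square on `(nIn/nOut)/(bIn/bOut)`, traits with ≥ 10 SNPs in
   the set), one-sided Fisher gene-set/oncogene enrichment, TF summit
   density (≥ 60% overlap rule, per Mbp) and 500-bp co-occupancy, 200-bin
   meta-profiles, knockdown H3K27ac depletion against WT–WT background
   variation (1%/99% percentile rule), target-downregulation permutation
   tests, and conservation scoring.

A seeded synthetic-data generator (`generate_dataset()`) plants enhancer
clusters, somatic effects, expression/methylation couplings, TF summits and
SNP enrichments with full ground truth, so the entire pipeline is testable
offline; `truth_report()` scores any stage against the planted truth.

## Worked example

```r
library(somaSE)

sim <- generate_dataset(simulation_design(seed = 1))   # 6 lines, 8 pairs, 2 x 10 Mb
res <- run_pipeline(sim$dataset, pipeline_config(seed = 1))

nrow(res$enhancers); nrow(res$se_catalog)
#> 353 predicted enhancers, 33 super-enhancers, 166 typical

res$somatic
#> somatic_calls: 33 super-enhancers
#>      gain      loss unaltered  inactive
#>        13         9         6         5
#>   (gain 39%, loss 27%, unaltered 18%, inactive 15%)

head(res$recurrence[order(res$recurrence$rank_product), 1:4], 3)
#>                id rank_product p_empirical n_present
#> SE_00016 SE_00016           72  0.00009999         6
#> SE_00023 SE_00023         1080  0.00049995         6
#> SE_00019 SE_00019         2880  0.00119988         6

head(res$links[!is.na(res$links$gene_id), ], 3)
#>      se_id   gene_id tss_pos distance is_closest_gene_overall
#> 1 SE_00001 gene_0281  362050    23125                    TRUE
#> 2 SE_00002 gene_0208  530450    27775                    TRUE
#> 3 SE_00003 gene_0012 1263050    14450                    TRUE

res$expression$p_value    # gain vs unaltered expression (one-sided Welch)
#> 7.46e-11
res$snp_enrichment[, c("trait", "enrichment_ratio", "chi2_p")]
#> trait_enriched_1..3: ratios 2.75-3.07 at p < 1e-17 (planted 3x)
#> trait_null_1..2:     ratios 0.85-1.28, not significant
res$tf_cooccupancy
#> 0.824  (fraction of TFA summits with a TFB summit within 500 bp)

truth_report(sim$truth, res)$super_enhancers
#> recall 1.0, precision 0.91, per-region Jaccard 0.986-0.99
```

The rank-product table says SE_00016 is the most consistently strong
super-enhancer across the six cell lines (product of its six per-line ranks
= 72, permutation p ≈ 1e-4); the somatic table reproduces the planted class
structure exactly (accuracy 1.0 against truth); the SNP table recovers the
planted 3x trait enrichments while the null traits stay flat.

`write_results(res, "out/")` writes the BED catalogs and the fixed-order
tab-separated call tables; `write_dataset()` / `load_dataset()` round-trip
the full dataset directory. A minimal CLI covers the same surface:

```sh
soma-se simulate --out data/ --seed 1
soma-se run --data data/ --out results/ --seed 1
```

## Documentation

The methods vignette (`vignettes/somatic-super-enhancers.Rmd`) describes
the models and assumptions, every tunable threshold with its default and
rationale, what the synthetic world does and does not emulate, numerical
conventions and tie-breaks, and known limitations.
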