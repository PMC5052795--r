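---
title: "Somatic super-enhancer analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic super-enhancer analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaSE)
```

## The problem

Super-enhancers are clusters of enhancers carrying exceptionally high
H3K27ac, and tumours reorganize them: some are somatically *gained* relative
to matched normal tissue, some *lost*, others unaltered or simply inactive
in primary tissue. somaSE implements the complete analysis chain from binned
histone-mark signal to somatic super-enhancer biology: signal
quantification, predicted-enhancer calling, super-enhancer stitching and
ranking, cross-line recurrence, tumour/normal classification, gene
assignment, and the downstream enrichment statistics (GWAS SNPs, gene sets,
TF occupancy, knockdown depletion). Because the intended cohort-scale data
cannot ship with a package, a seeded generator builds a synthetic cohort
with planted ground truth so every stage is testable end to end.

## Signal model and quantification

All tracks are fixed 50-bp bin count vectors over a shared genome model.
Signal over a region is quantified as

\[
\mathrm{RPKM} = \frac{\text{reads in region} \times 10^9}
                     {\text{library size} \times \text{region width (bp)}},
\]

with partial bins prorated by overlap fraction. ChIP signal is corrected by
subtracting the matched input RPKM, floored at zero. Subtraction (rather
than a ratio) is the package's documented choice where the correction
formula is not standardized; it matches common super-enhancer-ranking
practice and preserves the additive units the somatic thresholds are
expressed in.

### Empirical background and the small-genome caveat

Presence of a region in a sample is an empirical test: its corrected RPKM
must strictly exceed the 99th percentile (type-1 empirical quantile) of
100,000 random fixed-width regions. On a gigabase genome, enhancer
territory is well under 1% of the sampled space and that percentile sits at
the background ceiling. On a deliberately small synthetic genome the same
estimator breaks: with ~4% of base pairs inside planted peaks, the top 1%
of random regions all land in peaks and the "background" threshold rises to
peak level. `build_background()` therefore offers two estimators:

* `tail = "empirical"` — the literal q99 of corrected values (the presence
  contract, and what the calibration tests exercise);
* `tail = "symmetric"` — the null q99 estimated as \(-q_{01}\) of the
  *unfloored* chip − input difference. Under no enrichment the difference
  is symmetric around zero, and genuine peaks inflate only the positive
  tail, so the negative tail stays uncontaminated at any peak density.

The pipeline uses the symmetric estimator for candidate-calling and
promoter-activity thresholds, and the empirical one for presence calls.

### Candidate calling

The built-in caller is intentionally simple (external peak calls can be
supplied as BED): maximal runs of contiguous bins above a threshold, kept at
≥ 200 bp. Two practical refinements are applied by the pipeline, not by the
caller itself. First, the corrected per-bin signal is smoothed with a
5-bin (250 bp) centered moving average, emulating the locally correlated
coverage that 200-bp read extension produces on real data. Second, the
calling threshold is the background q99 times a stringency factor
(default 2): a per-window P < 0.01 rule over \(10^5\) windows would yield
~\(10^3\) false windows and flood run-length calling, while doubling the
threshold drops the per-window false-positive rate to ~\(10^{-5}\).

## Predicted enhancers, stitching, and the hockey stick

Candidates become predicted enhancers when they are distal — every covered
base at least 2.5 kb from every annotated TSS — and enhancer-like by the
aggregate H3K4me3/H3K4me1 ratio, \(\log_2((\mathrm{me3}+c)/(\mathrm{me1}+c))
\le 2.4\) with pseudocount \(c = 0.1\) (log base and pseudocount are package
choices; the 2.4 threshold is kept as printed). Predicted enhancers within
12.5 kb are stitched transitively into super-enhancer candidates.

Stitched regions are ranked by total input-corrected H3K27ac signal over
their constituents. The alternative of normalizing by the stitched extent
was considered and rejected: dividing by the gap-containing span makes a
single strong constituent outrank a genuine multi-constituent cluster,
which inverts the quantity the method is designed to detect (a
`normalize = "extent"` option retains the variant). The super/typical split
is the classic hockey stick: signals sorted ascending, rank and signal
rescaled to the unit square, cutoff at \(\max_i (x_i - y_i)\) (the slope-1
tangent point), ties broken to the larger index so borderline regions stay
typical; regions strictly above the cutoff signal are super-enhancers.
Per-line super-enhancers overlapping by ≥ 1 bp across lines are merged into
the non-redundant catalog; merged predicted enhancers outside catalog
territory are the typical enhancers.

Recurrence across lines uses rank products: within each line regions are
ranked by descending signal (average ranks on ties), the per-region product
of ranks is compared against a null built by independently reshuffling each
line's rank vector 10,000 times, and the empirical p-value uses the
(1 + hits)/(1 + permutations) estimator so it is never zero.

## Somatic classification

For each catalog super-enhancer and tumour/normal pair, with pseudocount
0.1 on the fold: a pair supports *gain* when fold ≥ 2 and the difference
exceeds 0.5 RPKM, *loss* mirror-image. Classes are assigned in order:
*inactive* when no primary sample (tumour or normal) reaches 0.5 RPKM
(max-based — the weakest requirement for activity, minimizing false
"inactive" labels); *gain* with ≥ 2 supporting pairs not outnumbered by
loss pairs; *loss* with ≥ 2 pairs; otherwise *unaltered*. When both
directions are recurrent the pair majority wins, ties to gain — conflicts
are essentially impossible under the planted effect sizes and are logged
when they occur. Swapping tumour and normal labels maps gain ↔ loss exactly
(up to exact ties, which the tie rule by construction sends to gain in both
orientations).

Methylation evidence is the per-pair mean beta difference over probes in
the region, compared gain-vs-loss by a one-sided Welch test; expression
evidence is the per-pair \(\log_2\) FPKM fold change of the linked gene
(differential flag: raw fold ≥ 2 and |difference| ≥ 0.5 FPKM), compared
gain-vs-unaltered; copy number is the length-weighted mean segment log
ratio thresholded at > 0.6 (gain) and < −1.0 (loss).

## Gene assignment

A promoter (TSS ± 500 bp) is active when its corrected H3K27ac exceeds the
1-kb background threshold in at least one sample of the analysis set
("any-sample"; a "majority" rule is available — the aggregation across
samples is not pinned down by any printed convention). Each super-enhancer
links to the active TSS nearest its centre (`floor((start+end)/2)`),
equidistant ties to the smaller coordinate, and records whether that gene
is also the nearest gene ignoring activity — on real data a large fraction
of links skip the closest gene, and the generator reproduces that
qualitatively through inactive decoy genes.

## Downstream statistics

* **SNP enrichment** — per trait, the ratio
  \((n_{in}/n_{out})/(b_{in}/b_{out})\) against a background SNP catalog
  with a 1-df chi-square (no continuity correction by default; flag
  available). Traits with fewer than 10 SNPs inside the region set are
  excluded, as printed.
* **Gene sets** — one-sided Fisher's exact test on the 2×2 table, shared by
  the oncogene and hallmark analyses.
* **TF occupancy** — sites counted when ≥ 60% of the site overlaps the
  region set (summits: membership), densities per Mbp; co-occupancy is the
  fraction of A summits with a B summit within 500 bp.
* **Meta-profiles** — 200 equal slices per region with prorated bin
  overlap; slice RPKM times slice width sums exactly to the region total
  (relative error < 1e-6).
* **Knockdown depletion** — analysis regions tiled into 1-kb subregions
  (width configurable; "subregion" has no printed definition). The
  background is the pooled distribution of pairwise WT−WT differences.
  Because the call statistic is mean(WT over m replicates) − KD, raw
  pairwise differences overstate the null spread (variance \(2\sigma^2\)
  versus \((1+1/m)\sigma^2\)); the pooled background is rescaled by
  \(\sqrt{(1+1/m)/2}\) so that the 1%/99% percentile rule is calibrated —
  an exchangeable pseudo-knockdown then flags ~2% of subregions, as the
  null calibration requires. `scale_background = FALSE` restores raw
  quantiles. Super-vs-typical depletion magnitude is compared with a
  one-sided Wilcoxon test.
* **Target downregulation** — observed downregulated count among genes
  linked to depleted super-enhancers, against 10,000 uniform redraws of the
  assignments from the expression universe (with replacement, matching a
  binomial null), (1+hits)/(1+n) p-value.
* **Conservation** — maximum track score within 500 bp of the region
  midpoint.

## The synthetic world

The generator plants everything the pipeline is supposed to find, with
defaults chosen once as a realistic small-scale analog and then left alone:

* genome 2 × 10 Mb at 50-bp bins; 300 genes (75% expressed; the rest are
  silent decoys with no promoter signal), minimum TSS spacing 4 kb;
* 120 enhancer clusters, 25% designed as super-enhancers. Typical clusters:
  1–3 constituents of 0.5–2 kb, gaps 1–12 kb. Super-enhancer clusters: 4–8
  constituents of 1.5–3 kb, gaps 1–3 kb. Constituent H3K27ac folds are
  10–20× background (typical) and 30–60× (super); H3K4me1 6–12× at
  constituents; promoters of expressed genes carry 8–16× H3K27ac and
  H3K4me3. Whole cluster extents stay ≥ 2.5 kb from every TSS and ≥ 13 kb
  from each other, so the distal filter never removes a true positive and
  distinct clusters never stitch together;
* counts are negative binomial (size 10) around 0.5 reads/bin, scaled by
  each track's log-normal library size (median \(10^7\)), so RPKM
  normalization is genuinely exercised; input tracks carry background only;
* somatic classes per cluster (gain 35%, loss 20%, unaltered 25%, inactive
  20%): gain multiplies the tumour peak by 3 in ~60% of pairs (min 3),
  loss by 1/3, inactive removes the peak from every primary sample;
  expression of the linked gene follows the somatic fold, methylation
  anti-correlates (Δβ = ∓0.2), TF summits concentrate in gain clusters
  (1/kb, 75% co-binding within 300 bp), and trait SNPs are enriched 3× in
  somatic clusters against a uniform background catalog;
* identical seeds give byte-identical written datasets.

What a green test does **not** establish: the generator has flat-top peaks,
independent bins (no fragment-length autocorrelation beyond the caller's
smoothing), no GC or mappability structure, no copy-number-driven signal
coupling, and planted effects comfortably above threshold. Green means the
algorithms implement their contracts and recover a well-posed world; it is
not evidence about detection power at marginal effect sizes.

## Numerical conventions

Coordinates are 0-based half-open everywhere internally (SNP catalogs,
1-based on disk, are converted at the I/O boundary); strand is ignored for
distances. Percentiles are type-1 (inverted CDF) throughout. Rank-product
comparisons run in log space with a 1e-12 tolerance to avoid overflow at
catalog scale. The hockey-stick tie rule, the nearest-TSS tie rule
(smaller coordinate), and the gain/loss conflict rule (majority, tie →
gain) are the deterministic tie-breaks. Degenerate inputs: all-equal
stitched signals warn and call nothing super; empty candidate sets, empty
catalogs and probe-free regions propagate as empty results or NA rather
than errors.

## Limitations

Read alignment, peak-caller sophistication (shape/FDR), batch correction,
chromatin-interaction validation, motif discovery and survival analysis are
out of scope. The somatic thresholds are applied exactly as printed; their
behaviour at shallow signal (e.g. the 0.5 RPKM inactive floor over very
short regions, where input-subtraction noise can exceed the floor) is a
property of the published rule, not of this implementation, and is why
cohort-scale conclusions should rest on recurrent, well-covered regions.
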