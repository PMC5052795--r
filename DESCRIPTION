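Package: somaSE
Title: Somatic Super-Enhancer Analysis from Binned Histone-Mark Signal
Version: 0.1.0
Authors@R:
    person("soma-se", "developers", email = "somase@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicted enhancer and super-enhancer
    analysis of tumour cohorts from fixed-bin (50 bp) histone-mark signal
    tracks. Quantifies H3K27ac/H3K4me1/H3K4me3 ChIP signal in RPKM with input
    correction, calls candidate enriched regions, applies distal and
    H3K4me3/H3K4me1 ratio filters to define predicted enhancers, stitches
    constituents into super-enhancer candidates and separates super-enhancers
    from typical enhancers by the ranked-signal hockey-stick cutoff, scores
    cross-line recurrence by rank products with a permutation null, classifies
    super-enhancers against matched tumour/normal pairs into somatic gain,
    loss, unaltered and inactive categories, assigns each super-enhancer to
    its nearest active transcription start site, and computes downstream
    statistics: GWAS SNP enrichment against a background SNP catalog, gene-set
    and oncogene enrichment, transcription-factor summit density and
    co-occupancy, binned meta-profiles, knockdown H3K27ac-depletion calls with
    an empirical background-variation null, and target-downregulation
    permutation tests. A seeded synthetic-data generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
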