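Package: padlockDM
Title: Differential Methylation Analysis for Targeted Bisulfite Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: End-to-end analysis of targeted (padlock-probe) bisulfite
        sequencing panels: quality control and normalization of
        cytosine-level methylated/unmethylated count matrices, robust
        per-cytosine linear modelling on shrunken M-values with
        residual-PCA surrogate variables and empirical-Bayes variance
        moderation, Fisher odds-ratio enrichment statistics over genomic
        elements, TSS-distance bins and pathways, per-gene summaries with
        robust rank aggregation across datasets, epigenetic aging-rate
        estimation, and cross-dataset concordance statistics. Includes a
        beta-binomial panel simulator with known ground truth for
        calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
        Sequencing, Software
RoxygenNote: 7.3.3
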