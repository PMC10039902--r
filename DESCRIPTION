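Package: methylscope
Title: Integrative DNA Methylation Array Analysis of Tumor Classes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline for DNA methylation array
    cohorts: probe-level preprocessing (platform intersection, exclusion
    filters, beta/M transforms), unsupervised class discovery (variance-ranked
    probe selection, hierarchical clustering, t-SNE embedding, bootstrap
    stability), copy-number inference from array intensity (recursive binary
    segmentation, gain/loss calling, genomic-index complexity scoring),
    global and context-stratified methylation quantification, differential
    methylation at probe and region level (probe-lasso region calling, signed
    cross-class intersection, hypergeometric gene-set enrichment), and
    Kaplan-Meier / log-rank survival comparison. Ships a synthetic-cohort
    generator with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    survival,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, CopyNumberVariation, Classification,
    DifferentialMethylation, Survival, MethylationArray
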