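Package: PanelProfiler
Title: Integrated Tumor-Only Genomic Profiling for Targeted Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for tumor-only targeted sequencing
    panels in head and neck squamous cell carcinoma and similar settings. Builds
    pooled-normal reference coverage models, computes per-bin log2 coverage
    ratios, segments them by circular binary segmentation, and assigns integer
    copy numbers and copy-state classes; detects allelic imbalance and
    copy-neutral loss of heterozygosity from heterozygous-SNP variant allele
    frequency deviations; filters raw variant tables against population
    frequency and panel-of-normals rules; integrates mutations, copy states and
    LOH into per-gene biallelic-inactivation and actionability calls; and
    compares per-gene mutation frequencies between cohorts with exact
    hypergeometric tests and conditional maximum-likelihood odds ratios. A
    synthetic-cohort simulator with known ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
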