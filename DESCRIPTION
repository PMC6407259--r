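Package: cghcnv
Title: Array CGH Copy Number Variant Calling and Quantitative Trait Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of array comparative genomic hybridization
    (aCGH) log2-ratio data for copy number variation (CNV) studies in
    livestock cohorts. Provides exact penalized least-squares dynamic
    programming segmentation of probe-level log2 ratios, conservative
    threshold-based CNV calling (0.5 log2 over five probes) with length
    filtering and hemizygous chrX baseline handling, construction of CNV
    regions (CNVRs) by aggregating overlapping calls across samples,
    principal-component signal summarisation and Gaussian-mixture copy-number
    genotyping per CNVR, ordinary least-squares association of genotype dosage
    with quantitative traits (predicted transmitting abilities) under
    Bonferroni correction with variance-explained estimation, hierarchical
    trait clustering on association p-values, and interval annotation of CNVRs
    against gene models and QTL catalogues. A seeded synthetic-cohort
    generator with known CNV and phenotype structure makes every stage
    testable without microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
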