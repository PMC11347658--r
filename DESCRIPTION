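Package: donorwise
Title: Donor-Aware Differential Analysis and Motif Grammar Models for
    Single-Nucleus RNA and ATAC Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for multi-donor single-nucleus RNA-seq and
    ATAC-seq studies of solid tissue (developed around an adult human heart
    cohort). Builds transcription-factor motif-count by cell matrices from
    binary motif occurrences in accessible peaks, tests motifs, genes and
    cell-type proportions for covariate effects (age, sex, anatomical site,
    study) with negative-binomial and beta-binomial mixed models carrying a
    per-donor random intercept, runs preranked permutation gene-set
    enrichment, compares stage-specific motif enrichments, and fits elastic
    net models that predict cell-type pseudo-bulk expression from binary
    motif features in promoters and co-accessibility-linked distal sites.
    A synthetic-study generator with planted effects makes every stage
    testable without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    glmmTMB,
    MASS,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
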