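Package: phocidist
Title: Genomic and Morphometric Distinctness Analyses for Seal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the evolutionary distinctness of a focal
    pinniped population against related populations. Implements a SNP
    filtering chain (outgroup polarization, callability and repeat masks,
    missingness and invariant-site exclusion, physical thinning, derived
    allele count filtering), private derived-allele pattern statistics and
    covariance-based PCA, windowed genome-tree summaries of monophyly
    support, post-processing of isolation-with-migration trajectories into
    cumulative migration probabilities and threshold-crossing split-time
    proxies, and dental and tongue morphometric diagnostics (permutation
    tests, ROC analysis, crown-profile relief and cusp geometry). A
    synthetic-data module generates all input formats with known ground
    truth so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
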