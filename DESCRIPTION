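Package: dairyqtl
Title: Two-Stage Mixed-Model GWAS for QTL Discovery and Validation in Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-stage genome-wide association workflow for
    quantitative dairy-cattle traits: a discovery mixed-linear-model scan on a
    dense variant panel with variance components estimated once on the null
    model (REML via a single eigendecomposition of the genomic relationship
    matrix) and then fixed, definition of QTL regions with upper-third-of-peak
    confidence intervals (TOP-CI/EXT-CI), per-QTL variance explained
    (2p(1-p)b^2), budgeted candidate-variant selection prioritized by
    significance with functional-annotation tie-breaks, and confirmation of
    candidates in a statistically independent validation population scanned on
    candidates plus an array panel. A seeded synthetic-data generator
    (blockwise founder-haplotype genotypes with planted QTL,
    reliability-controlled pseudo-phenotypes, annotation labels) makes every
    stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
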