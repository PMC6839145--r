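Package: twindiff
Title: Paired Differential Expression and Methylation Integration for
    Discordant Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for transcriptomic studies of disease-discordant
    monozygotic twin cohorts. Implements TMM normalisation, paired
    negative-binomial GLM likelihood-ratio testing with Cox-Reid dispersion
    estimation, within-pair effect-size comparisons, rank-based permutation
    gene-set enrichment, surrogate variable estimation, and an integrative
    expression-methylation analysis combining spatially adjusted CpG p-values
    with expression p-values via the empirical Brown method. Includes a
    synthetic twin-cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
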