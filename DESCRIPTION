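Package: loytraj
Title: Mosaic Loss of Chromosome Y in Single-Cell RNA-Seq: Calling,
    Trajectories and X-Inactivation Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying mosaic loss of chromosome Y
    (LOY) in single-cell RNA-seq of peripheral blood mononuclear cells.
    Calls LOY per cell from male-specific-region (MSY) read counts produced
    by two independent counting sources, summarises donor clonality and its
    association with age and SNP-array clonal fractions, models LOY
    enrichment along pseudotime trajectories stratified into quantiles, runs
    two-part hurdle and proportion-expressing pseudobulk differential
    expression, analyses X-inactivation escape genes including a from-scratch
    implementation of Hartigan's dip test for XIST bimodality, fits
    LOY-by-pseudotime interaction models with donor random effects, and
    performs hypergeometric gene-set overrepresentation analysis.  Ships a
    synthetic-cohort generator with known ground truth so that every
    estimator can be exercised and calibrated without access to controlled
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
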