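Package: stratmeta
Title: Stratified-Control Meta-Analysis of Transcriptomic Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression workflow for drug-perturbation RNA-seq
    datasets in which a small treated group faces a large, heterogeneous
    pool of vehicle (DMSO) controls. Controls are stratified by principal
    component analysis and k-means with a clustering-stability suite
    (bootstrap Jaccard, prediction strength, proportion of ambiguous
    clustering), per-stratum drug effects are estimated with a
    negative-binomial Wald model adjusted for embedding covariates, and
    stratum effects are pooled by inverse-variance fixed-effect
    meta-analysis with explicit retention criteria. Downstream tools derive
    cross-dataset signatures, fold-change concordance networks, and
    hypergeometric over-representation results with comparator-specificity
    filtering. A synthetic-data generator with known ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
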