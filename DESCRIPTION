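Package: famepi
Title: Family-Based Evaluation of Two-Locus Statistical Epistasis in
    Disease Penetrance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing gene-gene interaction (statistical
    epistasis) between two SNPs in family-based cohorts where the outcome
    is the number of affected members per family. Provides a self-contained
    Poisson regression engine (iteratively reweighted least squares, log or
    identity link) with likelihood-ratio tests, AIC model selection and
    Wald rate ratios; dominant genotype coding and carrier contingency
    tables; a model ladder comparing single-locus, two-locus additive
    (main effects) and multiplicative (interaction) penetrance models;
    stratified rate ratios and epistasis-sign classification on both the
    multiplicative and additive scales; multiplex-family risk prediction
    from the fitted Poisson tail; and a synthetic family-cohort simulator
    with a deterministic contingency-table fixture so the whole pipeline is
    testable without access to individual-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
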