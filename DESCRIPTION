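Package: metabmi
Title: Metabolite Scores, Pathway Enrichment and Causal Mediation for
    Pre-Pregnancy BMI and Pregnancy Complications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds sparse partial least squares (sPLS) metabolite scores
    for maternal pre-pregnancy body mass index from blood metabolomics,
    transfers the scores across cohorts over overlapping metabolite sets,
    relates them to binary pregnancy complications through multivariable
    logistic regression with per-SD odds ratios, tests hypergeometric
    pathway over-representation of the selected metabolites, and isolates
    the metabolite subset mediating the BMI to gestational-diabetes
    association with a quasi-Bayesian causal mediation analysis wrapped in
    a backward-elimination loop.  Includes metabolomics preprocessing
    (missingness filtering, iterative random-forest imputation,
    log/centre/scale standardisation, iterative-PCA covariate imputation,
    twin de-duplication) and a synthetic-cohort generator with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
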