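Package: kinherit
Title: Familial Aggregation and Pedigree-Based Variance Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for family-based epidemiology of co-occurring traits:
    pedigree handling (PLINK .fam, LINKAGE and CSV dialects), relative-pair
    classification and additive genetic relationship matrices; recurrence
    risk ratios (lambda_R) for first-degree relatives and spouses with
    family-clustered inference, including cross-phenotype co-aggregation;
    univariate and bivariate average-information REML animal models for
    heritability and genetic, phenotypic and environmental correlations; a
    liability-threshold cohort simulator with known ground truth; and a
    config-driven pipeline assembling descriptive, aggregation and
    variance-component results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    sandwich,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
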