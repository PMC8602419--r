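Package: twinvar
Title: Classical Twin-Design Variance Decomposition and Polygenic-Score
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of twin cohorts: maximum-likelihood
    variance decomposition of quantitative traits into additive genetic,
    shared/dominance and unique environmental sources (saturated, ACE, ADE,
    AE and E models, with sex stratification and sex-limitation via a
    cross-sex genetic correlation), bivariate Cholesky decomposition yielding
    genetic and unique-environmental correlations between traits and the
    fractions of a phenotypic correlation they explain, descriptive tables
    with pair-clustered sex-difference tests and Cronbach's alpha, and
    polygenic-score regressions with cluster-robust (sandwich) inference.
    Includes a calibrated twin-cohort simulator with known variance-component
    structure that serves as a ground-truth oracle for the estimators, and a
    pipeline driver that produces report-style tables from a single
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    yaml
Config/testthat/edition: 3
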