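Package: twinace
Title: Biometric Modeling of Twin Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin design applied to questionnaire
    composites: simulation of monozygotic/dizygotic twin cohorts with known
    additive-genetic (A), shared-environment (C) and unique-environment (E)
    covariance structure plus Likert item responses with acquiescence bias;
    questionnaire preprocessing (acquiescence correction, composite scoring,
    Cronbach's alpha, age/sex residualization); full-information maximum
    likelihood fitting of ACE-family models to mixed paired and unpaired twin
    data with likelihood-ratio model comparison and profile-likelihood
    confidence intervals; multivariate Cholesky decomposition into genetic and
    environmental correlations and personality-shared versus unique variance
    fractions; and cluster-robust (GEE-style) phenotypic association with
    Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
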