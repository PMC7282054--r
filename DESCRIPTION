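Package: morphlink
Title: Linking Cortical Morphometry to Autism Symptom Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-track statistical pipeline for surface-based cortical
    morphometry in a 2x2 factorial design (22q11.2 deletion by autism
    spectrum disorder). Track one fits massively univariate vertex-wise
    general linear models for cortical volume, surface area and thickness
    and corrects cluster inference with random field theory for
    non-isotropic fields on a triangulated surface. Track two aggregates
    vertex maps to regional features, selects features by stepwise-AIC
    regression, and links them to the five Social Responsiveness Scale
    subdomains through canonical correlation analysis, including Wilks'
    lambda, Pillai's trace, Rao's F, Bartlett's sequential chi-squared
    tests, variate adequacy and redundancy, forward-model group-specific
    loadings, Tucker's congruence and Fisher-Z loading comparisons. A
    synthetic-cohort generator with planted vertex effects and a planted
    low-rank brain-behaviour link makes every stage testable without
    access to MRI data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Matrix,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    readr,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
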