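Package: moesubtype
Title: Mixture-of-Experts Subtyping of Alzheimer's Disease from Cortical
    Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers atrophy-based subtypes of Alzheimer's disease from
    regional cortical-thickness tables. Regional thickness is residualized
    against a cognitively-normal reference model (age, sex, education and
    intracranial volume), then a semi-supervised mixture of experts couples
    fuzzy clustering of patients with one max-margin linear patient-versus-
    control classifier per cluster, optimized alternately. Includes
    cross-validated model selection by classification accuracy, expert
    inner products and the fuzzy partition coefficient; cross-sectional
    subtype profiling (ANOVA, Dunnett and Tukey comparisons, chi-square
    tests, biomarker abnormality proportions, per-region effect-size maps);
    longitudinal subtype attribution and transition tables; and a synthetic
    ADNI-like cohort generator with planted atrophy patterns for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
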