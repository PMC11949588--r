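Package: cpmod
Title: Connectome-Based Predictive Modeling Across Perceptual Modalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for training and externally validating connectome-based
    predictive models (CPM) of sustained attention across perceptual
    modalities. Provides behavioral scoring of continuous performance tasks
    (gradual-onset and audio-visual variants, oddball reaction-time
    variability), run-level quality-control exclusions, functional-connectome
    construction and canonical edge vectorization, CPM edge selection and
    network-strength prediction, partial Spearman validation with nuisance
    covariates, permutation tests of modality specificity, hypergeometric
    edge-overlap tests, canonical-network contribution matrices, and a
    synthetic-cohort generator with planted predictive edges for end-to-end
    verification without fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
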