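Package: semgadapt
Title: Surface EMG Feature Extraction and Mixed-Model Analysis of Postural
    Perturbation Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel surface electromyography (sEMG)
    recorded during repeated postural balance perturbations. Provides
    zero-phase band-limiting and comb-filter preprocessing, perturbation-locked
    epoch segmentation, amplitude (RMS), spectral (median frequency),
    complexity (sample entropy, Higuchi fractal dimension) and
    probability-density-shape features based on affine registration of sample
    quantile functions to a Gaussian reference (central, left and right shape
    distances), confound screening and smooth-model adjustment, per-cell
    linear mixed-effects models with a Group by Trial interaction and Wald
    z inference, significance summarisation and trend annotation. A synthetic
    cohort generator with controllable group effects makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    mgcv,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
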