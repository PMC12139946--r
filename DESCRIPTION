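Package: braintrait
Title: Brain-Trait Association Across Regions, Networks, and Whole-Brain Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for asking which level of brain organization --
    single regions, canonical resting-state networks, or distributed whole-brain
    activation patterns -- carries information about negative affective traits
    such as neuroticism and its facets. Implements the theory-driven battery
    (region and network correlations with Holm correction, region-restricted
    partial least squares, split-half best-region confirmation, multivariate
    network models, neural-signature expression), a staged data-driven model
    search with repeated nested cross-validation, permutation testing and
    stratified hold-out validation, psychometric evaluation of trained patterns
    (split-half reliability, convergent and discriminant validity, within-person
    state decoding), virtual lesioning of regions and networks, and a multiverse
    sweep over design choices with random-forest importance and mixed-model
    variance decomposition. Includes one-sided correlation Bayes factors under
    stretched-beta priors, Fisher-z confidence intervals, and power analysis for
    hold-out samples, plus a calibrated synthetic-data generator reproducing the
    statistical structure such analyses face: strong per-person global activity
    offsets, highly correlated network activity between persons, strong
    within-person state signal, and weak distributed trait signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    ranger,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    pracma,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
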