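Package: synecv
Title: Synthetic Haematocrit and Extracellular Volume Estimation from Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting synthetic haematocrit (synHct) from
    pre-contrast blood-pool attenuation in cardiac computed tomography and
    deriving synthetic extracellular volume (synECV) without blood sampling.
    Implements the published literature and refitted baseline linear models,
    a combined sex- and body-mass-index-stratified model family with explicit
    routing and fallback policies, the covariate-influence procedure that
    selects stratifications (interaction-term testing, significance-gated bin
    enumeration, and sliding-window subgroup restriction), voxel-wise ECV map
    computation from registered volume pairs with blood-pool erosion, and an
    evaluation harness (mean absolute error, Pearson correlation with
    Fisher-z confidence intervals). A calibrated synthetic cohort and phantom
    generator reproduces the statistical structure of the study population so
    the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
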