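Package: nichecal
Title: Calibration, Selection, Projection and Extrapolation Risk for
    Maximum-Entropy Ecological Niche Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for presence-background ecological niche
    modelling: occurrence cleaning (coordinate-uncertainty filtering, spatial
    rarefaction, calibration/evaluation splits), accessible-area (M) masking,
    jackknife-based variable-set reduction, a regularized maximum-entropy model
    with the five classic feature classes (linear, quadratic, product,
    threshold, hinge), candidate-model calibration and selection by partial-ROC
    significance, omission rate at an acceptable-error threshold, and AICc,
    replicate-based median/range suitability surfaces, transfer to future
    climate scenarios with clamping, GCM-agreement composites, and
    mobility-oriented parity (MOP) extrapolation-risk analysis. Includes a
    virtual-species simulator (spatially autocorrelated climate fields, known
    truth suitability, occurrence sampling, pseudo-GCM futures) so the whole
    pipeline can be exercised and validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
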