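Package: ionarray
Title: Simulation and Analysis of Graphene Transistor Ion-Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for high-density electrolyte-gated graphene field-effect
    transistor (EGFET) ion-sensor arrays functionalized with ion-selective
    membranes. Provides a physics-based array simulator (Nernst and
    Nikolsky-Eisenman membrane response on a compact EGFET transfer-curve
    model, with device-to-device variation and yield), transfer-curve
    analytics (Dirac-point extraction, sensitivity, reversibility, response
    time), a single-solution profile-matching calibration that exploits
    device-to-device variation, ECDF-based synthetic-response generation for
    sensor-redundancy studies, and a Random Forest electronic-tongue pipeline
    for ion-type and concentration inference with SHAP-based feature
    attribution, ablation and device-subsampling analyses.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    class,
    cluster,
    e1071,
    kernlab,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
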