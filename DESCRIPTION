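Package: fusbeam
Title: Hybrid Angular Spectrum Beam Simulation and Thermometry Analysis for
    Transcranial Focused Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid 3D simulation of transcranial focused ultrasound with a
    1024-element hemispherical phased array. Maps CT Hounsfield units to
    acoustic property volumes, propagates per-plate complex pressure fields
    through heterogeneous skull models with a hybrid angular spectrum solver,
    integrates the Pennes bioheat equation to temperature-rise time series,
    and reproduces the MR-thermometry-side treatment analysis: focal-spot
    position and temperature metrics, treatment efficiency, skull density
    ratio, sonication selection, and robust calibration regression. Includes
    synthetic skull phantoms and noisy thermometry generators so the whole
    pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
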