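Package: mucosim
Title: Compartmental Pharmacokinetics of a Tenofovir Vaginal Gel with
    Neural-Net Mapping from Blood to Mucosa
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic compartmental pharmacokinetic simulator for a
    tenofovir (TFV) vaginal gel. Solves coupled one-dimensional unsteady
    diffusion-reaction equations for TFV across gel, epithelial and stromal
    layers with partition-coefficient interface conditions, a well-mixed
    blood compartment, and first-order intracellular conversion to tenofovir
    diphosphate (TFV-DP). Computes compartmental pharmacokinetic summary
    metrics (Cmax, tmax, AUC, C24) and the percent-protected
    pharmacodynamic time course with its t_lag and PP_max summaries. Runs a
    full-factorial host-variability cohort over epithelial thickness, gel
    dilution rate and stroma-to-blood clearance, and trains single-hidden-
    layer feedforward neural networks by Levenberg-Marquardt least squares
    to predict stromal PK/PD metrics from blood PK metrics. Includes a
    command-line pipeline (simulate, cohort, train, predict) with JSON
    configuration and CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
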