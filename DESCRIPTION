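Package: clleach
Title: Chloride Leaching, Residual Estimation and Safe KCl Dosing for
    Rain-Fed Potato Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing water-soluble chloride dynamics in layered
    field soils under rain-fed potato cultivation. Implements area-based
    chloride stock accounting (mg/kg to kg/ha), leaching-factor and
    residual-ratio budgets, a three-covariate linear model estimating residual
    soil chloride from cumulative rainfall, chloride application rate and clay
    content (with both inversions: required rainfall for a target content, and
    allowable dose under a given rainfall), a goodness-of-fit suite (Pearson r,
    R-squared, RMSE, NRMSE, PBIAS) with a banded rating rubric, quadratic
    rainfall-response and dose-response fitting, critical-rainfall and safe
    KCl-range solvers, and a calibrated synthetic field-trial generator so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
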