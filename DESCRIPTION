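Package: cdv0
Title: Dose-Response Potency Analysis for GARDskin Decision Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative skin-sensitization potency assessment from
    GARDskin dose-response experiments. Fits constrained four-parameter
    log-logistic models (fixed lower asymptote at the unstimulated-control
    decision value, negative slope) to per-chemical concentration series of
    classifier decision values, tests for concentration dependence with a
    likelihood-ratio no-effect test, and estimates cDV0 -- the lowest
    concentration at which the decision value reaches the positive
    classification threshold (DV >= 0) -- both from the fitted curve (with
    inverse-regression confidence intervals) and by local linear interpolation
    with optional running-median smoothing. Includes the geometric
    concentration-series designer used by the assay, a synthetic dose-response
    generator for validation studies, and benchmarking of cDV0 against LLNA
    EC3 and human NOEL reference potency data, including GHS 1A/1B
    sub-categorization and log-scale Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
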