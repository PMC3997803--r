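Package: micronue
Title: Microbial Nitrogen Use Efficiency from Isotope Pool Dilution and
    Stoichiometric Threshold Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates gross nitrogen transformation rates (gross organic
    nitrogen uptake, gross nitrogen mineralization, gross nitrification)
    from 15N isotope pool dilution time courses, computes microbial
    nitrogen use efficiency (NUE) and its stoichiometric context
    (carbon-to-nitrogen imbalance, stoichiometric homeostasis, the
    threshold elemental ratio and its carbon use efficiency mass balance),
    and fits the threshold models used to locate the switch between carbon
    and nitrogen limitation of decomposer communities: continuous
    two-segment (break-point) regression, a saturating rectangular
    hyperbola, single-predictor regression trees with one-standard-error
    pruning, and ordinary linear regression.  Includes a synthetic-data
    generator emulating a 93-sample litter and soil survey so that every
    stage of the pipeline can be tested by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    rpart
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
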