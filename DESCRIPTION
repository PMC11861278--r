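Package: depressdyn
Title: Compartmental Dynamics of Depression with Saboteurs: Calibration,
    Stability and Optimal Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a seven-compartment ordinary-differential-equation model
    of depression spread in which "saboteurs" (detractors who undermine others'
    mental health) both recruit by contact and aggravate primary depression.
    Provides the model right-hand side and its controlled extension, adaptive
    integration, the next-generation-matrix basic reproduction number and its
    closed form, normalized forward sensitivity indices (elasticities) and R0
    contour grids, closed-form and numerically continued equilibria with
    Jacobian-eigenvalue stability classification and Descartes sign bounds for
    the endemic total-population quintic, maximum-likelihood calibration of the
    contact and recovery rates to yearly prevalence series with Wald confidence
    intervals, a synthetic prevalence-series generator, and a Pontryagin
    forward-backward-sweep solver for three treatment controls with an A-G
    strategy comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    lhs,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
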