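Package: energytoggle
Title: Energy-Dependent Toggle-Switch Models of Cellular Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a two-gene regulatory circuit in which each
    gene self-activates and represses the other, and all expression rates are
    scaled by a sigmoidal function of intracellular energy (ATP) availability.
    Provides the governing ordinary differential equations with analytic
    Jacobian, multistart steady-state finding with eigenvalue-based stability
    classification, bifurcation sweeps over the scaled energy level,
    attractor-count landscapes over parameter planes, basin-of-attraction
    mapping, and geometric phenotype-transition distance metrics.  Named
    scenario presets reproduce the standard parameter regimes used to study
    how energy budgets modulate the number of cell fates a circuit supports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    minpack.lm,
    optparse
Config/testthat/edition: 3
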