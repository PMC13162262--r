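Package: eddycalc
Title: Benthic Ecosystem Calcification from Coupled pH and O2 Aquatic Eddy
    Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies benthic net ecosystem calcification from simultaneous
    proton (pH) and dissolved oxygen aquatic eddy-covariance flux measurements.
    Provides a seawater carbonate-system solver on the total pH scale (Lueker
    K1/K2, Dickson KSO4, Perez & Fraga KF, Lee total boron) with
    finite-difference proton-yield ratios; a turbulence flux-processing chain
    (planar-fit rotation, Reynolds decomposition with a running mean, time-lag
    alignment, 29-minute flux windows, cumulative-flux and cospectral quality
    control); inversion of paired proton and oxygen fluxes to net ecosystem
    calcification, daily NEC, and oxygen-based metabolism with propagated
    standard errors; an error-propagation sensitivity analysis for pH,
    alkalinity, and photosynthetic-quotient measurement errors; and a
    ground-truthed synthetic deployment generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
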