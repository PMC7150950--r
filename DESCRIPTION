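Package: fiberdep
Title: Lagrangian Transport and Deposition of Fiber Aerosols in Synthetic
    Airway Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the transport and deposition of micron-sized
    ellipsoid (fiber-shaped) aerosol particles in synthetic airway
    geometries under a dry-powder-inhaler inhalation maneuver. Builds
    idealized conducting-airway analogs (a constricted, bent upper-airway
    surrogate and a symmetric dichotomous bronchial tree), imposes analytic
    laminar velocity fields scaled in time by the inhalation waveform, and
    tracks one-way coupled particles under Stokes-regime anisotropic drag,
    shear-induced lift, gravity, and quasi-steady Jeffery rotation.
    Deposition is detected on wall contact including fiber-tip
    interception, classified by mechanism, and summarized as deposition
    efficiencies and dispersion indices over a grid of equivalent diameters
    and aspect ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
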