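Package: morphosim
Title: Quasi-Static Viscous Finite-Element Simulation of Early Vertebrate Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional quasi-static viscous finite-element simulator
    for early vertebrate tissue morphogenesis. Embryonic tissue is modelled
    as a slow viscous material (a Hooke-analog viscosity tensor relating
    stress to strain rate) on a Lagrangian moving triangle mesh, driven by
    composable boundary-force actuators: purse-string line tension, normal
    pressure, antagonistic shear pairs, tension gradients, extensional
    shear, and curvature-dependent negative surface tension (growth).
    Includes programmatic generators for the model domains (annulus wound,
    body rectangle with crenel placodes, rounded head contour), discrete
    boundary-curvature estimation, quality-triggered remeshing, an analytic
    quadrupolar potential-flow model of placode winding, scenario presets
    for wound closure, ear, mouth, neck-flexure, nasal-process and buckling
    experiments, and analysis utilities for closure-law fitting (linear vs
    exponential self-arrest) and shape metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    interp,
    deldir,
    mgcv,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
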