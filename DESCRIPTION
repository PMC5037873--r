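Package: retikin
Title: Compartmental Analysis of Plasma Retinol Tracer Kinetics and
    Beta-Carotene Bioefficacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based compartmental analysis of plasma retinol tracer
    kinetics after oral dosing with stable-isotope-labeled retinyl acetate
    and beta-carotene.  Implements a dual-arm six-component linear
    compartmental model with transport-delay elements, weighted nonlinear
    least-squares parameter estimation, steady-state estimation of vitamin A
    pool sizes and disposal rate, recycling and residence-time parameters,
    and relative beta-carotene bioefficacy by model-based and graphical
    area-under-the-curve ratio methods.  Includes a synthetic-cohort
    generator emulating the sampling design and population dispersion of a
    two-week dual-tracer study, and a quality-control screen for plasma
    isotope response curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
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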