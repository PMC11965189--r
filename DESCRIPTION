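Package: exhaustim
Title: Exhaustion-Structured Models of Tumour-Immune Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a family of tumour-immune interaction
    models in which cytotoxic T-cells are structured by their exhaustion level.
    Provides the exhaustion-compartment ODE system, its exact moment reduction
    to a three-variable system (total T-cells, mean exhaustion, tumour burden),
    steady-state and linear-stability analysis with fold and transcritical
    bifurcation tracking, one- and two-parameter bifurcation maps, a
    time-dependent treatment schedule acting on the exhaustion rate, and the
    continuum transport-equation limit solved analytically by the method of
    characteristics. Parameter sets can be supplied in dimensional or
    dimensionless form and converted between the two.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
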