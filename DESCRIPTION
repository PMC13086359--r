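Package: cryofront
Title: Axisymmetric Finite-Difference Simulation of Frozen-Zone Dynamics in
    Cryotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth and retreat of the frozen zone produced by a
    liquid-nitrogen cryoapplicator pressed against 5% gelatin hydrogel or
    layered biological tissue (skin, subcutaneous fat, muscle).  Solves the
    nonlinear axisymmetric heat equation with an explicit finite-difference
    scheme, temperature-dependent thermophysical properties, and the latent
    heat of the water phase change expressed as an effective heat capacity
    over the mushy temperature range.  Provides freeze and thaw stage
    scheduling, isotherm radius/depth tracking, logarithmic growth-law
    fitting, surface thermogram export, analytic validation oracles
    (semi-infinite erf cooling, the two-phase Neumann-Stefan solution), and a
    small command-line driver.
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
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
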