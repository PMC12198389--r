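Package: fmpes
Title: Force-Modified Potential Energy Surfaces for Polymer Mechanochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing mechanochemical activation barriers on
    force-modified potential energy surfaces (FMPES). Implements constant
    collinear pulling forces and a generalized harmonic uniaxial-compression
    potential (G-FMPES), composed additively onto a pluggable base potential;
    quasi-Newton minimization and dimer-method transition-state searches with
    Hessian-eigenvalue characterization of stationary points; scan drivers
    tabulating activation energy versus pulling force and versus compression
    force constant; built-in analytic benchmark surfaces (Mueller-Brown,
    quartic double well, a bead-spring flex-mechanophore toy); XYZ geometry
    I/O; and ultrasound acoustic dosimetry (intensity, linear-approximation
    acoustic pressure, FDA mechanical index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
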