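Package: carotdyn
Title: Surface-Hopping Dynamics and Trajectory Analysis for Carotenoid
    Photophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonadiabatic excited-state dynamics on analytic model
    potential-energy surfaces using the fewest-switches surface-hopping
    algorithm with locally diabatic electronic propagation and decoherence
    corrections, together with the trajectory-analysis toolchain used to
    characterise carotenoid photophysics in light-harvesting complexes:
    sequential kinetic fits of excited-state populations, bond-length
    alternation and dihedral descriptors of the conjugated chain,
    distortion indices, excited-state absorption spectra, and Coulomb
    couplings between chromophore transition densities represented as
    atomic transition charges. A synthetic-ensemble generator emulates
    the statistical structure of surface-hopping production runs so every
    analysis stage can be exercised without quantum-chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
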