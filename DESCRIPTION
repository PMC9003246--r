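Package: eesm
Title: Equivalent Energy Spring Model for Real-Time Soft-Tissue Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid soft-tissue material modelling that equates a
    non-Gaussian, Mullins-effect-capable strain energy density function
    with the stored energy of one-dimensional variable-stiffness springs.
    Provides the closed-form uniaxial stress laws (virgin and
    stress-softened branches with residual strains), conversion of the
    strain energy density into precomputed stretch-dependent spring
    stiffness tables, a spring-mass mesh simulator whose edges are
    equivalent-energy spring elements, estimation of the material
    constants from uniaxial loading/unloading stress-stretch curves, and
    a synthetic-data generator emulating cyclic tensile tests on liver
    parenchyma.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
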