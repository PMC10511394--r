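Package: cbqlv
Title: Constituent-Based Quasi-Linear Viscoelastic Modelling of Arterial Walls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the nonlinear viscoelastic mechanics of
    arteries tested under biaxial (pressure-diameter-axial force) loading.
    Implements a constituent-based quasi-linear viscoelastic (cbQLV)
    framework in which Fung's quasi-linear viscoelasticity is applied
    separately to the elastin-dominated isotropic matrix and to four
    collagen fibre families of a thin-walled vessel, each with its own
    continuous-spectrum reduced relaxation function. Provides the
    four-fibre-family strain energy function with constituent deposition
    stretches, hereditary-integral stress evaluation for arbitrary
    deformation histories, thin-wall equilibrium and pressure-driven
    inverse solves, dynamic-to-quasi-static stiffness ratios, loss
    factors and dynamic-to-static modulus grids, a synthetic biaxial
    testing protocol generator, and the three-step multistart
    least-squares parameter-estimation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
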