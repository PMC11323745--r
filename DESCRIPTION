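Package: scleraAPDI
Title: Finite-Element Simulation of Air-Puff Deformation Imaging of the Sclera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward and inverse finite-element modelling of air-puff deformation
    imaging (APDI) of the rabbit sclera. Builds a parametric quarter-globe geometry
    (elliptical sclera with axially graded one-term Ogden stiffness and a spherical-cap
    cornea), meshes it with quadratic hexahedra, applies intraocular pressure with an
    iterative stress-free (zero-pressure geometry) procedure, and loads it with a
    quasi-static spatially distributed air puff. Computes the deformation statistics
    apex displacement (AD), central-peripheral ratio (CPR) and asymmetry ratio (AR)
    from sagittal surface profiles, runs one-at-a-time sensitivity and random-sampling
    parametric studies, and estimates the scleral material coefficient from AD-vs-IOP
    data by bounded scalar minimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    rlang,
    generics,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
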