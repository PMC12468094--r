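Package: cxlsim
Title: Patient-Specific Finite-Element Simulation of Corneal Cross-Linking
Version: 0.1.0
Authors@R: person("cxlsim", "developers", role = c("aut", "cre"),
    email = "cxlsim@example.org")
Description: Biomechanical pipeline for predicting corneal-geometry changes
    induced by standard and customized corneal cross-linking (CXL) in
    keratoconus. Generates synthetic keratoconic topographies, builds
    quadratic tetrahedral corneal meshes, evaluates a depth-varying
    two-fiber-family Holzapfel-Gasser-Ogden hyperelastic law with
    keratoconus weakening and CXL stiffening multiplier fields, recovers
    the stress-free configuration by fixed-point pre-stressing, inflates
    the cornea to physiological intraocular pressure with a nonlinear
    finite-element solver, and quantifies outcomes through tangential
    curvature, biconic keratometry and agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
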