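Package: aortafem
Title: Cohesive-Zone Finite Elements for In-Plane Aortic Dissection Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static nonlinear finite-element framework for simulating
    in-plane tear propagation in the dissected aorta. Implements the
    Holzapfel-Gasser-Ogden (HGO) fiber-reinforced nearly-incompressible
    hyperelastic model for the arterial wall, a bilinear mixed-mode cohesive
    traction-separation law with quadratic stress initiation and power-law
    energy failure for the lamellar interface, virtual peel, direct-tension
    and shear calibration experiments, and an idealized bilayer cylindrical
    aorta pipeline that predicts the critical propagation pressure, the
    propagation direction, and the mode of interfacial damage. Includes a
    semi-analytic extension-inflation solver for verification, opening-angle
    residual-stress prestrain, VTK and CSV export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
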