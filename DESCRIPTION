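Package: thromboflow
Title: Phase-Field Modeling of Thrombus Biomechanics in Blood Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully Eulerian phase-field model of the mechanical interaction
    between flowing blood and a porous, viscoelastic thrombus. Couples an
    incompressible Navier-Stokes solver with a Cahn-Hilliard phase equation,
    Eulerian deformation-gradient (Kelvin-Voigt) elasticity, and a
    Darcy-Brinkman drag with volume-fraction-dependent permeability (Davies'
    law). Includes virtual calibration experiments (a permeation chamber for
    permeability and an oscillatory shear cell for the elastic shear modulus
    via storage/loss-modulus loop analysis) and a coarse-grained
    force-coupling-method platelet aggregation stage whose output seeds the
    phase field.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
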