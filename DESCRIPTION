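Package: blebmech
Title: Biomechanical Stability Analysis of Lung Parenchymal Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the fluid-structure dynamics of quasi-spherical
    lung parenchymal lesions (blebs) whose rupture triggers spontaneous
    pneumothorax. Couples an isotropic hyperelastic membrane wall with
    pulsatile breathing pressure and pleural-fluid loading into a
    nondimensional ODE system; provides closed-form equilibria and
    Jacobian-based instability criteria, finite-energy-limiter rupture
    modelling, collagen-elastin remodelling kinetics, and an image-analysis
    pipeline that estimates material parameters from a deforming tissue
    boundary and classifies angular sectors as stable or unstable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    png,
    optparse
Config/testthat/edition: 3
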