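Package: scafmatch
Title: Inverse Design of Anisotropic Porous Bone Scaffolds by a Self-Learning
    Convolutional Surrogate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing 2D porous bone scaffolds whose homogenized
    plane-stress elasticity matrix matches that of a target trabecular-bone-like
    structure. Includes a synthetic generator for trabecular-bone-like grayscale
    slices with the CT-to-modulus preprocessing chain (Gaussian smoothing,
    maximum-intensity projection, density calibration, ash-density and
    density-modulus mapping), a voxel-based heterogeneous plane-stress finite
    element homogenizer (three canonical loading scenarios under kinematic
    uniform boundary conditions), a discrete 36-variable wall-lattice scaffold
    parameterization with an invertible 6x6 matrix encoding, a weighted
    stiffness-matching objective, a small convolutional neural network surrogate
    trained on finite-element labels, a self-learning archive-based optimizer,
    an exhaustive periodic-cell baseline, and Bland-Altman, R-squared and
    quartile reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
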