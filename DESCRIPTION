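Package: bggreg
Title: Rigid Medical Image Registration with Bounded Generalized
    Gaussian Mixtures
Version: 0.1.0
Authors@R:
    person("bggreg", "maintainers", email = "bggreg@example.org",
           role = c("aut", "cre"))
Description: Intensity-based rigid registration of 2-D grayscale medical
    images.  The joint intensity scatter of a reference/floating image
    pair is modelled by a mixture of generalized Gaussian distributions
    truncated to the bounded intensity range of 8-bit images, fitted by
    expectation-maximization with Monte-Carlo corrections for the
    bounded support and a damped Newton step for the shape parameters.
    Motion parameters (translation and rotation) are estimated by a
    linearized increment solve alternating with density estimation
    inside a coarse-to-fine multiresolution pyramid.  Includes a
    synthetic phantom generator, a perturbation/sweep protocol, the
    average-pixel-displacement (PAD) error metric, plain PNG image I/O
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
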