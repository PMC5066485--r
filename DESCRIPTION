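Package: wallcreep
Title: Viscoelastic Creep Analysis and Calibration Tools for Plant Cell
    Wall Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the four-element Kelvin-Voigt-Burgers viscoelastic model
    to creep-extension curves of plant stem segments by multi-start
    constrained nonlinear least squares, estimates xyloglucan molecular
    mass from gel-permeation elution profiles via dextran log-linear
    calibration, performs linear standard-curve quantification of sugars
    and oligosaccharides, and computes carpel morphometry with two-sample
    comparisons. A synthetic-data generator with known ground truth
    emulates the instrument outputs for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
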