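Package: helixbend
Title: Bending Elasticity of Double-Stranded Nucleic Acids from Base-Pair
    Step Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the elastic properties of double-stranded RNA (and
    other duplex nucleic acids) from base-pair step-parameter trajectories:
    tilt, roll and twist stiffnesses and twist-bend coupling by inversion of
    the cumulative-angle covariance matrix, the worm-like-chain bending
    persistence length by a quadratic fit to the bending-angle distribution,
    the bending-anisotropy parameter, and linear temperature trends of all of
    these across a temperature series. Ships a Gaussian rigid-base-pair
    trajectory generator with declared ground truth so every estimator can be
    validated end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
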