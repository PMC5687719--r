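Package: fluolapse
Title: Colony Growth and Fluorescent Expression Analysis from Plate Timelapse Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analyzes timelapse RGB image stacks of agar plates bearing
    fluorescent bacterial colonies. Colonies are located by multiscale
    Laplacian-of-Gaussian blob detection on a temporal sum projection,
    their areal growth is fitted with a logistic model to obtain maximal
    specific growth rates, per-colony fluorescent reporter expression
    rates are estimated with a dilution correction from smoothing-spline
    derivatives of the mean intensity per unit area, and colonies are
    classified by strain from the angular signature of their red and
    green channel totals. A seeded synthetic plate simulator with full
    ground truth supports validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
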