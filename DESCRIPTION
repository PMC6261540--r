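Package: vorofield
Title: Voronoi-Image Classification of Early-Glaucoma Visual Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating early-glaucomatous from control visual
    fields measured by standard automated perimetry. Arbitrary test patterns
    (OCTOPUS G1, Humphrey 24-2, or user-supplied charts) are rasterized into
    61x61 voronoi images in which every pixel takes the sensitivity deviation
    of its nearest tested location. A compact convolutional neural network is
    trained on these images and compared against the classical global indices
    MD (mean defect) and sLV (square-root loss variance), their combination,
    and a flat neural network, under subject-grouped k-fold cross-validation
    scored by average precision. SmoothGrad and region-averaged (piece-wise)
    saliency maps explain individual classifications. A synthetic visual-field
    generator with arcuate, nasal-step, paracentral and diffuse defect
    archetypes makes the whole pipeline exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
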