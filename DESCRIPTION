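Package: fibriltrace
Title: Morphometry of Amyloid Fibrils in AFM Topography Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies amyloid fibril length, height, and surface coverage
    from atomic force microscopy (AFM) height maps. Implements masked
    background flattening (plane, line-by-line, and feature-masked row-wise
    second-order polynomial subtraction), Gaussian modelling of the
    background pixel-height histogram, connected-component feature detection
    with branch-aware skeleton length measurement, per-condition aggregation
    (means, standard errors, kernel density summaries), and a synthetic AFM
    scene generator with per-object ground truth for validating every stage
    of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
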