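Package: spatialtime
Title: Distance-Gradient Analysis of Spatial Transcriptomics Around a
    Marked Tissue Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Region-referenced analysis of array-based spatial
    transcriptomics for trauma-induced heterotopic ossification and
    similar focal lesions. Computes a "SpatialTime" axis (per-spot
    minimum distance to a manually marked region, min-max scaled to
    [0,1]), classifies spots as cell-type positive or negative from
    label-transfer prediction scores, builds binned and smoothed
    expression or score profiles along the axis with peak, trend and
    crossing detection, quantifies collagen fibril alignment in
    grayscale microscopy images via an averaged nematic (orientation)
    tensor, and applies an automatic parametric/non-parametric
    test-selection scheme for group comparisons. Ships synthetic-data
    generators (spot lattices, prediction-score fields,
    negative-binomial count gradients, fibril images with known
    orientation concentration) so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    tiff,
    yaml,
    methods,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    car
Config/testthat/edition: 3
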