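Package: speckle4d
Title: Burst-Mode 4D Optical Coherence Microscopy Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for burst-mode 4D (x, y, z, t) optical coherence
    microscopy time-lapses of cell spheroids embedded in collagen gels. Synthesises
    label-free 'cell' and 'collagen' channels from temporal speckle statistics
    (mean and standard-deviation burst projections), removes lateral stage drift by
    sub-pixel volumetric cross-correlation of peripheral sub-volumes, segments the
    cell body by median filtering, Otsu thresholding and 4D region growing, and
    tracks collagen matrix deformation with a multi-resolution Thirion demons
    deformable registration. Includes a coherent speckle phantom simulator with
    full ground truth (cell masks, displacement fields, drift, depth background)
    for end-to-end validation, plus closed-form optical-design and raw-data
    accounting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
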