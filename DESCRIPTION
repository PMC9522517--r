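Package: pricklr
Title: Region-Partitioned Spot Detection and Annotation for Tongue Prickles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classic computer-vision toolkit for annotating prickles (enlarged
    fungiform papillae appearing as small red spots) on segmented tongue
    images. Provides two-pass connected-component mask refinement, automatic
    partitioning of the tongue into root, center, tip and margin areas, a
    multi-threshold blob detector with repeatability grouping and
    area/circularity/convexity/inertia shape filters parameterized per region,
    redmean chromatic-aberration color filtering against reference prickle
    colors, Labelme-dialect bounding-box import/export, detection and
    segmentation evaluation metrics with per-region reports, coordinate-wise
    grid search for detector parameters, and a seeded synthetic tongue-scene
    generator with full ground truth for testing every stage without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
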