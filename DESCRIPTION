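Package: glandseg
Title: Seeding-Searching-Ensemble Gland Segmentation for H&E Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and segments intestinal glands in hematoxylin-eosin stained
    histology images. For every seeding point on a uniform grid, a closed smooth
    contour is found as a cyclic shortest path in a polar multi-column graph
    (naive and divide-and-conquer solvers); the per-seed contours are ensembled
    into a boundary probability map, from which non-overlapping segmentation
    proposals are produced by watershed. Proposals are pruned, described by
    intensity statistics and histogram-of-oriented-gradients features, scored by
    a random-forest regressor against a Jaccard-overlap target, then refined by
    a boundary-resource re-weighting step and a greedy region-merging step.
    Includes a synthetic scene generator with ground truth, PASCAL-VOC style
    detection metrics, pixel-level segmentation metrics, and a leave-one-image-out
    cross-validation harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    png,
    tiff,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
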