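Package: spinecobb
Title: Unsupervised Spinal Segmentation and Cobb Angle Measurement via Local Centers of Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments the spinal column in anteroposterior radiographs with an
    unsupervised local-center-of-mass (LCM) clustering method and measures the
    Cobb angle of the resulting center curve by a purely geometric chord /
    apex / perpendicular construction. Provides the exact O(N) recurrence for
    the 1D local center of mass with a brute-force oracle, its 2D extension by
    orientation sampling and tracker convergence, spine-mask extraction with
    Canny edge detection and center-curve smoothing, segmentation evaluation
    metrics (accuracy, sensitivity, specificity, Dice), a synthetic spine
    phantom generator with analytic ground truth, and a batch pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    data.table,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
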