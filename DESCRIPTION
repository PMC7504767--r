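Package: actland
Title: Quantitative Comparison of Three-Dimensional Activity Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds three-dimensional activity landscape (AL) models of
    compound datasets and compares them quantitatively through image
    features. Compounds are projected into a two-dimensional chemical
    reference space by metric multidimensional scaling of Tanimoto
    fingerprint distances, a coherent potency surface is interpolated by
    Gaussian process regression with a Matern-plus-White kernel, and the
    surface is rendered as a red-yellow-green potency heatmap. Heatmaps
    are featurized on a fixed 56 x 60 grid into an eight-category cell
    intensity distribution, and pairs of landscapes are compared by
    symmetric relative entropy and cosine distance. Includes a synthetic
    dataset generator with controlled structure-activity-relationship
    continuity and discontinuity (activity cliffs) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
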