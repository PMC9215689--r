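Package: shapeback
Title: One-Back Shape Comparison Workbench for Visual and Haptic Psychophysics
Version: 0.1.0
Authors@R: person("Shapeback", "Maintainers", email = "maintainers@shapeback.dev",
    role = c("aut", "cre"))
Description: Tools for studying how people judge whether two abstract 2D
    shapes are the same. Generates random blob-union stimulus shapes,
    computes a battery of shape-dissimilarity metrics (curvature
    distribution, aspect ratio, area, convex-hull area, compactness,
    turning-function distance, intersection-over-union and Hausdorff
    distance, the latter three with presented-orientation and
    rotation-optimized variants), simulates one-back same-different
    sessions with a configurable logistic observer, ranks metrics by
    binomial-GLM AIC against a random baseline, and runs a Monte Carlo
    baseline analysis of finger-shape contact over perimeter touchpads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
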