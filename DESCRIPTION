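Package: pattquant
Title: Quantification of Melanistic Spot Patterns from Body-Region Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts binary melanistic spot patterns from colour photographs
    of single body regions using per-region robust-background (Niblack)
    thresholding, cleans and classifies the detected spots, computes fourteen
    geometric pattern indices per region, and compares patterns in the
    resulting 14-dimensional pattern space with two squared distances: the
    standard Mahalanobis distance and a developmental-noise weighted
    Euclidean distance whose weights are estimated from left-right front-leg
    differences. Includes permutation tests for within- versus
    between-individual pattern variation, index correlation matrices,
    principal component analysis, coefficients of variation, replicate
    measurement-error summaries, a sides-by-individuals ANOVA for
    fluctuating asymmetry, and a synthetic spotted-pattern generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    tools,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
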