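Package: revcorrnet
Title: Reverse-Correlation Analysis of Weighted Brain Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating group-discriminative connections in weighted
    structural brain networks by reverse correlation. Provides connectivity
    matrix input/output and density thresholding, weighted graph metrics
    (clustering, efficiency, path length, modularity, rich-club/feeder/local
    connection strengths) summarised as areas under the curve across a density
    grid, normalised mutual information between modular and rich-club
    partitions, a multilayer perceptron trained with scaled conjugate
    gradients, randomised-network generation from a patient-minus-reference
    difference matrix with NMI-based selection, classifier filtering and
    edge-frequency aggregation, the accompanying group statistics
    (t, chi-square, rank-sum, rank ANCOVA, FDR), and a synthetic cohort
    generator with planted edge-cluster effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
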