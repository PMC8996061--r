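Package: phytochunk
Title: Class-Dependent Chunk Sampling for Point-Cloud Segmentation of Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for battling class imbalance in the semantic segmentation
    of 3D plant point clouds. Training samples ("chunks") are built by
    sampling anchor points per organ class -- either proportionally to the
    class distribution or proportionally to its inverse -- and attaching each
    anchor's k nearest neighbours. The package provides imbalance diagnostics
    based on Shannon entropy, coverage chunking of test clouds, majority-vote
    merging of overlapping chunk predictions, a full IoU/precision/recall
    evaluation suite with Wilcoxon significance labels, a procedural
    generator of labelled cucumber-like point clouds, and a pluggable
    segmenter contract with a fast nearest-centroid baseline so the whole
    pipeline can be exercised end to end without a deep network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
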