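Package: salt
Title: Hierarchical Segmentation with Softmax over Arbitrary Label Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for hierarchical multi-organ segmentation built around a
    conditional softmax over arbitrary label trees. Provides rooted label-tree
    parsing and validation with adjacency, reachability and sibling matrices
    and a bitwise path encoding; the tree-structured activation that chains
    sibling-group softmax probabilities along root paths; a hierarchy-aware
    hybrid loss (path cross-entropy plus tree soft Dice) with support for
    sparse slice annotations; hierarchical Dice and normalized surface Dice
    evaluation with bootstrap confidence intervals; label-harmonization
    operators (merge, region split, "other"-node completion, annotation
    fusion) that force heterogeneous segmentation sets into a single-parent
    tree; deterministic CT preprocessing (reorientation, isotropic resampling,
    Hounsfield-unit normalization, random crops) with NIfTI input and output;
    and seeded nested-phantom generators for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
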