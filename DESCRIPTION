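Package: dcemoco
Title: Motion Correction and Landmark-Based Evaluation for Hepatic DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise motion correction for dynamic contrast-enhanced MRI of
    the liver and the landmark machinery to evaluate it. The registration
    minimizes a normalized gradient fields (NGF) distance with curvature
    regularization, preceded by a rigid preregistration that can be
    restricted to a coarse automatic liver segmentation. Evaluation tools
    cover annotation-scheme planning, confidence-interval based sample
    sizing, closest-of-two landmark distances, inter-observer distances,
    deformation-field folding detection via tetrahedral decomposition,
    time-cut images, and two-stage grid search of the registration
    parameters. A synthetic 5-phase abdominal phantom generator with known
    ground-truth motion and simulated two-annotator landmark noise makes the
    whole pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
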