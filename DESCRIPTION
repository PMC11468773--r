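Package: tomomine
Title: Molecular Pattern Mining and Few-Shot Particle Localization in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage toolkit for exploring the molecular content of
    cryo-electron tomograms and localizing particles from a handful of
    annotations. Stage one proposes candidate positions with a
    difference-of-Gaussians pyramid and 3D non-maximum suppression, learns a
    self-supervised contrastive embedding of tilt-averaged/central-slice patch
    pairs with a Siamese network, and groups the embedding by over-clustering
    for label-based coordinate selection. Stage two trains a per-slice UNet
    with 3D fusion as a voxel-level center detector using a non-negative
    positive-unlabeled focal risk, debiased supervised and self-supervised
    contrastive regularization, and a consistency loss; globular targets are
    extracted by max-pooling non-maximum suppression and tubular targets by
    distance-graph grouping, second-order polynomial fitting, curvature and
    residual filtering, and uniform resampling. Includes a ground-truthed
    synthetic tomogram generator (soft spheres, curved tubes, membranes,
    fiducials, missing wedge, tilt projections) and radius-tolerant greedy
    matching metrics, so the whole pipeline runs end-to-end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
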