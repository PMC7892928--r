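Package: e2dseg
Title: Extended-2D Consensus Segmentation of Bilateral Brain Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for segmenting small bilateral brain structures (such as
    the hippocampus) in 3D T1-weighted MRI. Three orientation-specialized 2D
    encoder-decoder networks are trained on extended-2D patches (a target
    slice plus its two neighbours as channels), their probability volumes are
    fused by activation averaging, thresholded, and cleaned by keeping the two
    largest connected components. Includes the soft Dice, generalized Dice and
    boundary (signed-distance) training losses with an epoch-annealed mixing
    schedule, NIfTI input/output with reversible canonical reorientation,
    runtime patch sampling with augmentation, stratified hold-out and k-fold
    protocols, per-side Dice/precision/recall evaluation, and a seeded
    synthetic phantom generator (including unilateral resection phantoms) so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    EBImage,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
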