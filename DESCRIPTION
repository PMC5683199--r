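Package: endogeo
Title: Geometry-Aware Stereo Endoscopic Surface Reconstruction and AR Overlay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline stereo-endoscopy pipeline for minimally invasive
    surgery scenes: feature-based stereo SLAM (constant-velocity pose
    prediction, RANSAC rigid alignment, keyframe selection and Huber-robust
    bundle adjustment), dense ZNCC disparity estimation with Huber-L1
    variational smoothing, incremental world-space surface meshing, and
    geometry-aware augmented-reality operations (surface picking, anchored
    labels, geodesic measurement and area highlighting on the reconstructed
    mesh). Includes a synthetic stereo-endoscopy scene generator with
    ground-truth poses and depth for quantitative evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
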