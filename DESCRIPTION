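Package: leafpheno
Title: Leaf Phenotyping from Branch-Level Lidar Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating single-leaf phenotypic traits from
    branch-level terrestrial lidar point clouds of fruit trees.  The
    pipeline covers point-cloud preprocessing (statistical outlier
    removal, voxel-grid thinning, farthest point sampling, invertible
    cube normalization), single-leaf instance extraction by flat-kernel
    mean-shift clustering, per-leaf estimation of inclination angle
    (least-squares plane fitting), leaf length and width (greedy midrib
    fitting on a k-d neighbourhood walk), and leaf area (surface
    triangulation with Heron's formula), together with the standard
    semantic- and instance-segmentation evaluation metrics (per-class
    precision/recall/F1/IoU, mean coverage, instance precision and
    recall at an IoU threshold).  A synthetic branch-and-leaf generator
    with analytic ground truth makes every stage testable without scan
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
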