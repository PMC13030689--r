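Package: pelvimark
Title: Automatic Anatomical Landmark Localization on 3D Pelvic Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for localizing six posterior pelvic
    anatomical landmarks (bilateral posterior superior iliac spines, bilateral
    iliac crests, L1 and L4) on raw 3D body-surface point clouds: a
    point-cloud segmentation network extracts the posterior pelvic region of
    interest, a rotation-regression network canonicalizes the pose, and a
    second segmentation network labels 10 mm landmark regions whose centroids
    give the landmark coordinates. Includes a compact set-abstraction /
    feature-propagation point network engine with manual backpropagation and
    Adam, rigid-geometry utilities (SVD projection to the rotation group,
    Euler conversions, canonical-pose construction), training objectives with
    oracle-tested gradients, evaluation metrics (IoU, recall, error
    distributions, subject-level confidence intervals), repeatability
    statistics (pooled STD, CV, ICC(2,1) with F-based confidence intervals), a
    deterministic synthetic pelvic-surface generator with ground-truth
    landmarks, and point-cloud I/O (PLY, OBJ, XYZ, landmark CSV).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
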