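Package: kneeval
Title: Validation Metrics for X-Ray-Based 3D Knee Bone Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Accuracy validation pipeline for 3D knee bone surface models
    reconstructed from plain-film X-rays, evaluated against CT-derived
    ground-truth segmentations. Provides mask-to-mesh conversion via
    isosurface extraction, STL/NIfTI/NRRD input-output, point-to-point
    iterative closest point registration, global and landmark-region
    root-mean-square surface error, simulated total knee arthroplasty
    resection planes with cut-contour error, anatomical-axis (TEA, PCA,
    MLTA) angular-deviation statistics against inter- and intra-observer
    baselines, and a synthetic bone-model generator with known error
    structure for end-to-end verification without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RANN,
    RNifti,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
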