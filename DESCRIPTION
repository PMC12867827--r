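Package: casnet
Title: Curvature-Aware Cardiac MRI Segmentation Networks with Multi-Scale
    Context and Cross-Attentive Skip Connections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements CASNet, an encoder-decoder segmentation network for
    short-axis cardiac MRI that augments a U-Net backbone with a Multi-Scale
    Context Block at the bottleneck, Cross-Attentive Skip Connections in
    place of naive concatenation, and a curvature-aware training loss that
    penalises the squared Frobenius norm of the predicted probability map's
    spatial Hessian. Includes a synthetic short-axis cardiac phantom
    generator, the full seven-metric evaluation suite (Dice, recall,
    accuracy, precision, Jaccard, Hausdorff distance, mean absolute contour
    distance), a CPU training harness with an ablation runner, and PNG/NIfTI
    dataset input/output. All forward and backward passes are implemented
    with BLAS-backed im2col convolution kernels, so no GPU or external deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png,
    RNifti,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
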