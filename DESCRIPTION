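Package: pneumonet
Title: Attention-Enhanced Residual Networks for Pneumonia Detection in
    Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Binary pneumonia-versus-normal classification of chest
    radiographs with a residual convolutional network augmented by
    side-branch attention blocks (convolutional dimensionality reduction,
    deconvolutional upsampling, element-wise fusion) and a
    class-count-normalized focal loss for imbalanced training sets. Ships
    a deterministic synthetic radiograph phantom generator emulating the
    radiographic signs of pneumonia (infiltrates, nodules, consolidation,
    density change, pleural thickening) so the full training and
    evaluation pipeline runs without clinical data, plus confusion-matrix
    metrics, an AdamW training loop with a step learning-rate schedule,
    an ablation runner, and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    caret,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
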