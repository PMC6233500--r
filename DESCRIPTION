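Package: srtexture
Title: Sparse-Representation Texture Radiomics for Multi-Modal Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomics analysis of multi-modal ultrasound images built on sparse
    representation theory. Per-class texture dictionaries are learned with the
    K-singular value decomposition (KSVD) algorithm from image patches, combined
    into a feature extraction dictionary (FED), and region-of-interest patches are
    sparse-coded against the FED with orthogonal matching pursuit (OMP); pooled
    absolute coefficients form the per-case feature vector. Features are screened
    by an iterative sparse-representation selection scheme and classified with a
    class-weighted support vector machine, evaluated by leave-one-out
    cross-validation with ROC/AUC metrics and bootstrap confidence intervals.
    Includes a seeded synthetic generator of two-class multi-modal texture images
    (grayscale and pseudo-color) so the full pipeline can be exercised end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
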