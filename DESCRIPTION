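Package: cemclass
Title: Classification of Confocal Laser Endomicroscopy Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated classification of confocal laser
    endomicroscopy (CEM) frame sequences of the colonic mucosa into
    healthy, inflammation and cancer (dysplasia) tissue states.
    Provides informative-frame quality control by gray-level histogram
    skewness, local binary pattern (LBP) patch-histogram texture
    features with a linear SVM classifier, a compact convolutional
    neural network trained from scratch, a transfer-learning scaffold
    with convolutional-layer freezing, redundancy-aware training-set
    selection by k-means clustering of first-order frame statistics,
    and evaluation harnesses for cross-subject and cross-sample
    training strategies. Includes a seeded procedural simulator of
    crypt-texture frame sequences for benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    e1071,
    png,
    EBImage,
    withr,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
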