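Package: qcxr
Title: Hybrid Classical-Quantum Classification of Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating hybrid classical-quantum
    transfer-learning classifiers for binary cardiomegaly detection on
    chest radiographs. Provides a dense statevector simulator for
    parameterized quantum circuits with analytic parameter-shift
    gradients, classical and quantum classifier heads over a pluggable
    feature extractor, the full training protocol (augmentation, freezer
    schedule, Adam), k-fold evaluation with paired statistical
    comparison, normalized global effective dimension analysis of the
    quantum layer, Grad-CAM++ saliency with automated trustworthiness
    assessment, and a synthetic radiograph generator parameterized by
    cardiothoracic ratio for fully reproducible experiments without
    access to licensed clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
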