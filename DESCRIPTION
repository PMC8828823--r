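Package: scintimet
Title: Multiclass Classification of Whole-Body Bone-Scan Scintigrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying whole-body bone-scan
    (SPECT scintigraphy) studies into no-metastasis, adenocarcinoma-metastasis
    and non-adenocarcinoma-metastasis classes. Provides anterior/posterior view
    aggregation by critical-point alignment and pixel-wise addition, bounded
    rotation/translation augmentation, a residual convolutional classifier with
    a hybrid channel-and-spatial attention mechanism (forward and backward
    passes implemented natively with compiled im2col kernels), patient-grouped
    train/test splitting, a full multiclass evaluation suite (one-vs-rest
    precision/recall/specificity/F1, macro and micro ROC/AUC), and a synthetic
    scintigram phantom generator so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    png,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
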