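Package: mammocad
Title: Radiomics and Transfer-Learning CAD Pipelines for Breast Lesion
    Classification on Mammographic Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates two computer-aided diagnosis (CAD)
    schemes for classifying breast mass lesions on 150x150-pixel
    mammographic regions of interest: a radiomics branch based on an
    adaptive multi-layer topographic region-growing segmenter followed by
    handcrafted morphology, density, texture and wavelet features reduced
    by principal components and classified with a polynomial-kernel
    support vector machine; and a deep-transfer-learning branch expressed
    as a backbone-agnostic finetuning protocol with a small built-in
    convolutional surrogate.  Includes four score-level fusion models,
    ROC analysis with an ordinal-likelihood binormal maximum-likelihood
    fit and DeLong comparisons, and a synthetic lesion phantom generator
    so the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    pROC,
    jsonlite,
    yaml,
    tiff,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
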