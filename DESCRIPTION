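Package: fibroscar
Title: Radiomics and Raman Chemometrics for Cardiac Fibrosis Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for label-free assessment of fibrotic
    cardiac tissue. Implements IBSI-conform 2D radiomic feature extraction
    (152 features per channel) from two-channel multiphoton microscopy planes
    (second harmonic generation and two-photon excited fluorescence), binary
    healthy-versus-pathologic classification with minimum-redundancy
    maximum-relevance feature ranking, SMOTE class balancing and a
    heterogeneous classifier ensemble over unique Monte-Carlo folds, and
    PLS-DA chemometrics for multiclass (muscle, necrotic, granulated,
    fibrotic) classification of Raman microspectra. A seeded synthetic-data
    generator emulates the class-dependent fiber texture and spectral band
    structure of fibrotic myocardium so that every stage is testable without
    access to tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    signal,
    Matrix,
    glmnet,
    randomForest,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
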