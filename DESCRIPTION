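Package: ceusradiomics
Title: Interpretable Radiomics for Contrast-Enhanced Ultrasound Liver Cines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Motion-robust quantification of contrast-enhanced ultrasound
    (CEUS) cine loops for benign/malignant characterization of focal liver
    lesions. Provides linearization of log-compressed contrast data,
    automatic square ROI construction around manual lesion masks,
    correlation-based valid-frame filtering with fiducial frame selection
    (wash-in, peak, wash-out), pixel-wise time-intensity-curve perfusion
    maps, ring-kernel spatiotemporal similarity maps (spectral coherence,
    correlation, mutual information), moving-window gray-level texture maps
    (GLCM, GLRLM, GLSZM, NGTDM), radiomic summary-statistic feature tables,
    two-stage feature filtering, and an imbalance-aware repeated nested
    cross-validation classification bench with permutation feature
    importance and the corrected resampled t-test. A synthetic dual-view
    cine simulator with known kinetic ground truth supports end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    Rcpp,
    e1071,
    randomForest,
    caret,
    pROC
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
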