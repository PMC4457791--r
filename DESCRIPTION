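Package: pepClassify
Title: Serum Peptidome MALDI-TOF Profiling and Mutation-Status Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for peptide mass fingerprinting of serum MALDI-TOF spectra
    and for building mutation-status classifiers from them. Implements the
    full workflow: spectral preprocessing (total-ion-current normalization,
    affine recalibration on prominent common peaks, Savitzky-Golay smoothing,
    top-hat morphological baseline subtraction, SNR-based peak detection and
    zero-level peak-area integration), per-peak differential statistics,
    quick-classifier, supervised prototype (LVQ) and genetic-algorithm k-NN
    model construction with repeated random-split cross-validation, blinded
    classification, and clinical concordance and survival evaluation
    (sensitivity/specificity/kappa, response tables, Kaplan-Meier and
    log-rank). A calibrated synthetic-data generator produces cohorts of raw
    spectra with linked clinical outcomes so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    signal,
    pracma,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    withr,
    optparse,
    knitr,
    rmarkdown
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
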