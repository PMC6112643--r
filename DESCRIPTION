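Package: ehgtools
Title: Uterine Electrohysterogram and Tocogram Analysis for Preterm-Birth
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization and classification of uterine records composed
    of abdominal electrohysterogram (EHG) signals and an external tocogram
    (TOCO).  Provides a zero-phase Butterworth filter bank over four disjoint
    analysis bands (0.08-1.0, 1.0-2.2, 2.2-3.5 and 3.5-5.0 Hz), per-band
    sample entropy, median frequency and normalized spectral peak amplitude
    features, separability criteria and sequential forward feature selection
    with frequency-based aggregation, class balancing (SMOTE, ADASYN) with
    quadratic discriminant analysis under repeated stratified
    cross-validation, readers and writers for WFDB-style record files, and a
    synthetic uterine-record simulator emulating contraction bursts,
    maternal respiration and the maternal cardiac component with harmonics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pROC,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
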