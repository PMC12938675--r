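Package: gdeeg
Title: Task-Based Occipital EEG Biomarkers of Gaming Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-channel occipital EEG
    (O1/O2) biomarker studies of Gaming Disorder. Provides a labelled
    synthetic EEG cohort generator with band-structured oscillatory content
    and injectable group effects; zero-phase Butterworth/notch preprocessing
    with epoch-wise amplitude artifact rejection and retention accounting;
    multilevel Daubechies-4 discrete wavelet decomposition into canonical
    EEG bands; spectral, temporal, Hjorth and entropy feature extraction in
    concatenated or segment-wise aggregation modes; Welch t / Cohen's d /
    Benjamini-Hochberg effect screening; and a leakage-safe
    leave-one-subject-out evaluation of five classifiers with Wilson score
    intervals and a LOSO-preserving permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rpart,
    randomForest,
    e1071,
    class,
    tibble,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
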