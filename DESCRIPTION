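Package: semgFatigue
Title: Muscle Fatigue Recognition from Multi-Channel Surface EMG
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising lower-limb muscle fatigue from
    multi-channel surface electromyography (sEMG). Provides a seeded
    simulator of cyclic-exercise sEMG with planted muscle-synergy
    structure and a controllable fatigue trajectory; zero-phase
    Butterworth band-pass, power-line notch and envelope extraction;
    muscle-synergy analysis by non-negative matrix factorisation with
    variance-accounted-for (VAF) model selection and dominant-channel
    ranking; sliding-window extraction of eight time-domain,
    frequency-domain and nonlinear fatigue features; min-max
    normalisation, equal-length resampling and stratified
    cross-validation splits; a self-attention (Transformer-encoder)
    sequence classifier with recurrent (LSTM) and gradient-boosted-tree
    baselines; and an evaluation layer with confusion-based metrics,
    ROC/AUC, permutation-sampling Shapley attribution and
    Friedman/Nemenyi model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
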