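Package: distractr
Title: Detecting Fatigue-Induced Inattention from Wearable ECG and GSR Signals
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting physical-fatigue-induced
    inattention from single-channel wearable electrocardiogram (ECG) and
    galvanic skin response (GSR) recordings. Provides heart rate variability
    (HRV) feature extraction (Pan-Tompkins QRS detection, Lomb-Scargle
    spectral analysis, Poincare and entropy measures), continuous
    decomposition of electrodermal activity into tonic and phasic
    components with skin conductance response (SCR) scoring,
    Shapiro-Wilk-gated paired-condition statistics, and leave-one-subject-out
    evaluation of SVM, KNN, LDA and random forest classifiers with
    t-ranked backward feature elimination. A synthetic paired-condition
    cohort generator with a ground-truth channel makes every stage testable
    without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    MASS,
    quadprog,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
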