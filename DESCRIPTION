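Package: momdecode
Title: Multivariate Decoding and Error Prediction for Multiple-Object
    Monitoring MEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multiple-object monitoring (MOM)
    vigilance experiments recorded with magnetoencephalography. Generates
    task schedules, behavioural outcomes with a configurable vigilance
    decrement, and synthetic multi-sensor epochs; performs time-resolved
    and distance-binned linear discriminant decoding with trial-grouped
    cross-validation; computes representational dissimilarity matrices and
    RDM-based informational connectivity between sensor groups; predicts
    single-trial behavioural errors from accumulated classifier evidence
    with leave-one-subject-out threshold transfer; and evaluates effects
    with Jeffreys-Zellner-Siow Bayes-factor t-tests and Bayes-factor
    ANOVA model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
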