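Package: eadyn
Title: Dynamic Arterial Elastance from Arterial Pressure Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting arterial pressure responsiveness to fluid
    challenge in mechanically ventilated patients. Computes pulse pressure
    variation (PPV), stroke volume variation (SVV, via a systolic-area
    pulse-contour surrogate) and their ratio, dynamic arterial elastance
    (Ea), from arterial pressure waveforms; applies preload-dependence and
    hypotension gating and the MAP-increase responder rule; and evaluates
    discrimination with ROC curves, DeLong confidence intervals, Youden
    optimal cut-offs and AUC-based (Hanley-McNeil) sample-size computation.
    Includes simulators for ventilated arterial waveforms and hemodynamic
    cohorts with analytically known ground truth, so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
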