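Package: ibsacoustics
Title: Bowel-Sound Acoustics for Irritable Bowel Syndrome Classification
Version: 0.1.0
Authors@R: person("Marshall", "Acoustics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation, detection and diagnostic modelling of abdominal
    bowel sounds. Generates reproducible synthetic cohorts of four-channel
    abdominal recordings with ground truth, detects and segments bowel-sound
    events into burst trains, extracts time- and frequency-domain acoustic
    features, trains an L2-penalised logistic classifier producing an IBS
    Acoustic Index (cut-off 0.5), and evaluates it with leave-one-out and
    k-fold cross-validation, out-of-bag bootstrap and full diagnostic-accuracy
    metrics with confidence intervals. Fed/fasted group effects on sound
    quantity density and summed amplitude are tested with a random-intercept
    linear mixed model fitted by profiled maximum likelihood.
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
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
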