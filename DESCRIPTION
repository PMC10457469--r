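Package: eegbrainage
Title: Brain-Age Modelling from Frontal EEG Recorded During General Anaesthesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating brain age from four-channel frontal EEG
    recorded during stable propofol or sevoflurane anaesthesia. Implements
    stable-segment selection via the 95 percent spectral edge frequency
    (SEF95), Welch power spectra and band-limited channel covariance
    features with tangent-space vectorisation, nested stacked ridge
    age-prediction models compared under Monte Carlo cross-validation,
    mixed-effects models of the age-related decline of log EEG power,
    and logistic models linking brain age to intraoperative burst
    suppression. A synthetic cohort generator with known ground truth
    emulates the statistical structure of anaesthesia EEG so that the
    whole pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    sandwich,
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
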