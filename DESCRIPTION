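Package: cspseizure
Title: Patient-Specific Seizure Prediction from Scalp EEG with Common
    Spatial Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-specific epileptic seizure prediction from multichannel
    scalp EEG. Overlapping epochs are spatially filtered with common spatial
    patterns (CSP), summarised as log-variance features, and classified as
    preictal or interictal with a closed-form linear discriminant; a
    median-smoothed run-length rule converts the classifier output into
    alarms, which are scored against seizure annotations with horizon-based
    sensitivity, false-waiting-time specificity, false prediction rate and
    prediction time, alongside periodic and Poisson chance predictors.
    Includes a reader for EDF recordings and CHB-MIT-style seizure
    annotation summaries, a covariance-contrast synthetic EEG generator so
    the full pipeline is testable without clinical data, and a
    leave-one-recording-out evaluation driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
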