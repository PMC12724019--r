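Package: hfatools
Title: Interictal High-Frequency Activity Biomarkers for Epilepsy Surgery Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interictal high-frequency activity (HFA) events in
    intracranial EEG with four established automatic detectors (short-time
    energy, short line length, Hilbert envelope, and the Montreal Neurological
    Institute baseline method), quantifies per-event morphology (duration,
    multitaper spectral power, peak frequency, normalized spectral entropy),
    trains and validates a gradient-boosted seizure-onset-zone probability
    model with a pseudo-label permutation null, and evaluates
    resection-completeness summary measures against postoperative seizure
    outcome. Includes a synthetic intracranial EEG cohort generator with
    ground-truth events, electrode labels, resection masks and outcomes so the
    whole pipeline is testable without patient data, plus compact EDF
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pROC,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
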