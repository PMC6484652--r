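Package: raforecast
Title: Forecasting Rheumatoid Arthritis Disease Activity from Longitudinal EHR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to forecast a rheumatoid-arthritis patient's next-visit disease
    activity state (controlled vs uncontrolled CDAI) from longitudinal electronic
    health record event tables. Implements cohort definition from diagnosis,
    medication, laboratory and CDAI tables; fixed-interval (120-day) window
    featurization of sparse clinical histories; a small, regularized recurrent
    (gated recurrent unit) forecaster with a fully dense surrogate; outcome-posterior
    and change-posterior baseline classifiers; evaluation statistics including DeLong
    AUROC confidence intervals, grouped permutation importance, confident-and-wrong
    and subgroup analyses, learning curves and t-SNE confusion plots; cross-hospital
    transfer and fine-tuning experiments; and a calibrated synthetic EHR generator so
    the entire pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
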