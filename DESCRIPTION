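Package: flowMRD
Title: Automated Flow-Cytometry Minimal Residual Disease Quantification
    with Patient-Specific RBF-SVM Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies minimal residual disease (MRD) in acute myeloid
    leukemia flow-cytometry specimens by training a patient-specific
    soft-margin support vector machine with a radial basis function kernel
    on diagnosis blasts (label 1) versus pooled healthy-donor events
    (label 0). Provides FCS 3.0 list-mode and CSV event-table input and
    output, a seeded synthetic-cytometry generator with spiked rare
    populations at known fractions, stratified event subsampling with
    largest-remainder quotas, saved-range feature scaling re-applied at
    prediction time, (C, gamma) grid search under stratified k-fold
    cross-validation, per-specimen MRD-fraction prediction, a
    conventional-gating comparator (2-D gates combined by logical AND),
    and method-agreement statistics (paired t-test, Pearson correlation,
    Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
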