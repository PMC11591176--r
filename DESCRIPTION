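Package: beatwise
Title: Beat-Wise ECG Representations for Detecting Reduced Left
    Ventricular Ejection Fraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying which parts of the 12-lead
    electrocardiogram carry the signal a convolutional classifier uses to
    detect reduced left ventricular ejection fraction (LVEF < 50%).
    Provides a synthetic 12-lead ECG cohort generator with analytically
    known fiducials and configurable class-dependent waveform effects, a
    beat-wise preprocessing pipeline (QRS detection and delineation,
    3-second strip oversampling, single-beat extraction with T-end
    padding, intra-beat partial segments, two-beat channel stacking, lead
    subsetting, train-statistics standardisation), a configurable
    ten-layer one-dimensional convolutional network classifier with MixUp
    augmentation and class-weighted cross-entropy, stratified four-fold
    cross-validation with a fixed test fold, case-level evaluation, and a
    per-lead contribution analysis over lead-subset ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
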