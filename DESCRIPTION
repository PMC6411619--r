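Package: fpvs
Title: Frequency-Tagged EEG Analysis for Fast Periodic Visual Stimulation
    Oddball Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of fast periodic visual stimulation
    (FPVS) oddball electroencephalography experiments. Provides a synthetic
    generator for frequency-tagged EEG cohorts with known ground truth
    (6 Hz base stimulation, 1.2 Hz oddball, 1/f background noise), a
    preprocessing chain (segmentation, zero-phase Butterworth band-pass,
    decimation, blink screening, channel interpolation, common average
    reference), amplitude-spectrum statistics (signal-to-noise ratio,
    baseline-corrected amplitude, noise-window z-scores), harmonic
    selection and region-of-interest response summation, split-plot
    repeated-measures ANOVA with Greenhouse-Geisser correction,
    severity-score correlation, and leave-one-out cross-validated linear
    classification (LDA, logistic regression, linear SVM) with permutation
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    glmnet,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
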