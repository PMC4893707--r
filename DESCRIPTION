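Package: swdmap
Title: Time-Frequency Mapping and Random-Field Inference for Spike-Wave Discharges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how focal cortical interventions
    alter spike-wave discharges (SWDs) in multi-channel local field potential
    recordings. Provides a calibrated synthetic GAERS-like session generator,
    SWD spike/event detection with adaptive analysis windows, sliding-window
    Welch power and magnitude-squared coherence on a 4-20 Hz / 0.1 Hz grid,
    pre-event baseline z-normalization, linear seizure-time rescaling, Gaussian
    map smoothing, random-field-theory corrected pixel-level inference on
    pooled time-frequency maps, 6-8 Hz band summaries with repeated-measures
    two-way ANOVA and post-hoc tests, interictal FFT band statistics, and the
    interlaced-microbeam transection geometry (stacked slab thickness,
    strip-intersection footprint, rotating-calipers width).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
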