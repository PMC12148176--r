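Package: tremorlink
Title: Ocular Microtremor Periodicity and the Critical Flicker Fusion Threshold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the periodicity of fixational eye movements to
    the critical flicker fusion threshold (CFFT). Provides a synthetic gaze
    generator (alternating fixations and saccades with ocular drift,
    microsaccades and a 70-150 Hz microtremor), gaze-velocity kinematics with
    a direction-reversal probability statistic, normalized cumulative power
    spectra, empirical mode decomposition with Hilbert-Huang instantaneous
    frequency distributions, psychophysical detection bookkeeping for
    two-target flicker trials, Mann-Whitney group-separation scans over the
    frequency grid, and an imbalance-aware decision-tree classifier of
    high- versus low-CFFT participants with nested cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
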