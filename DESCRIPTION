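Package: lrpfrac
Title: Fractionating Choice Reaction Time with the Lateralized Readiness
    Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for splitting choice reaction time into premotor and
    motor intervals using the lateralized readiness potential (LRP).
    Provides a synthetic flanker-task EEG cohort generator with known
    ground truth, a preprocessing chain (mastoid re-referencing,
    zero-phase Butterworth band-pass and notch filtering, segmentation,
    regression-based ocular correction, four-rule artifact rejection),
    double-subtraction LRP derivation with segmented-regression onset
    scoring, behavioral trial cleaning and winsorization, correlation and
    commonality analyses, a dual-mediator path model of age effects on
    reaction time with delta-method indirect effects and fit indices, and
    Monte Carlo power estimation for the mediation paths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
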