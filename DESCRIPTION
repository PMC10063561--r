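Package: biozbp
Title: Cuffless Blood Pressure Estimation from Ring Bioimpedance Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for cuffless beat-to-beat blood
    pressure estimation from finger bioimpedance plethysmography. Provides a
    synthetic hemodynamic signal generator built on an exponential arterial
    pressure-volume compliance model, carrier (lock-in) I-Q demodulation and
    Butterworth band-pass conditioning of the raw sensor voltage, beat
    segmentation with morphology-consistency metrics (ensemble standard
    deviation, spectral signal-to-noise ratio, dynamic time warping), fiducial
    point detection and a 15-feature per-beat descriptor, AdaBoost.R2
    regression of systolic and diastolic pressure with K-fold and
    leave-one-subject-out evaluation graded against AAMI and BHS criteria,
    and an analytic half-space reciprocity (lead-field) model of tetrapolar
    electrode sensitivity with a Cole-Cole tissue dispersion evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
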