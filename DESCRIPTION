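Package: ecgshift
Title: Sensitivity of the ECG Waveform to Electrode Placement and Motion
    Artifacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how displacing the Einthoven/Mason-Likar electrodes
    over the torso and back distorts the electrocardiogram, and how motion
    artifacts interact with placement.  A simplified bidomain
    FitzHugh-Nagumo heart embedded in a voxelized passive volume conductor
    generates surface ECGs at a reference position and at six displaced
    positions on front and back; a synthetic volunteer-cohort generator
    emulates ambulatory recordings; and a signal-comparison stack
    (ensemble-average ECG, segment-coefficient model, dynamic time warping,
    signal-to-noise ratio, percentage difference/similarity) measures the
    resulting waveform distortion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    deSolve,
    graphics,
    jsonlite,
    methods,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
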