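Package: festwin
Title: Desk-Scale Digital Twin for Functional Electrical Stimulation of the Forearm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates transcutaneous functional electrical stimulation (FES) of
    the human forearm at muscle-specific resolution. Builds a parametric layered
    volume conductor (bone, anisotropic muscle, fat, skin) with hydrogel surface
    electrodes, solves the quasi-static potential on a voxel grid, seeds
    muscle-specific regions of interest with myelinated nerve fiber populations
    drawn from a bimodal diameter distribution, and predicts fiber activation
    with the linear cable model and the activating function. Aggregates fiber
    verdicts into muscle recruitment, generates strength-duration and
    intensity-activation curves, and implements the calibration pipeline that
    selects muscle-specific activation thresholds from relative differences to
    experimental strength-duration curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
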