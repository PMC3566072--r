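Package: whitefront
Title: Whitening-Front Tracking for Crack-Extension Resistance Curves in
    Miniature Bend Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates crack-extension resistance curves (J-R and K-R
    curves) for sub-millimetre single-edge-notched bend specimens from
    three-point-bend videography. Frames are registered by subpixel
    DFT-upsampled cross-correlation, the stress-whitening (damage) zone is
    segmented on difference images, and the whitening front is used as an
    effective crack tip. Nonlinear fracture-mechanics quantities (J-integral
    decomposition and effective stress intensity per the ASTM E1820 single
    edge bend formulas) are computed from synchronised load-displacement
    channels, with a plane-stress finite-element correction for the apparent
    flexural modulus of a notched beam. A synthetic-data generator provides
    ground-truth videos and mechanics channels so the full pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
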