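Package: rotocell
Title: Self-Rotational Speed of Single Cells from Microscopy Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the self-rotational speed and motion trajectory of a
    single cell of interest in a multi-cell microscopy video. A background
    subtraction step segments moving cells, the cell of interest is tracked
    by nearest-centroid association, a reference frame whose appearance is
    most distinct from its temporal neighbours is selected automatically,
    and the per-frame maxima of the normalized correlation coefficient
    against the reference template yield once-per-revolution peaks.
    Parabolic interpolation of each peak gives sub-frame cycle timing, from
    which per-cycle speeds in rpm are computed. Also provides standalone
    electrokinetic utilities (time-averaged dielectrophoretic force, the
    real part of the Clausius-Mossotti factor for a shelled cell, and the
    self-rotation torque in a linearly polarized AC field) and a synthetic
    video generator with ground-truth manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
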