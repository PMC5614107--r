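Package: tomoctf
Title: Three-Dimensional CTF Correction and Weighted Back Projection for
    Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects the contrast transfer function (CTF) of tilted
    cryo-electron micrographs in three dimensions. Each tilt image is
    CTF-corrected at several defocus values spaced by a user-defined
    defocus step, and during weighted back projection every voxel is
    reconstructed from the image variants corrected at the defocus
    matching the voxel's height along the beam. Includes an astigmatic
    CTF model with phase-flip, multiplication and Wiener correction,
    defocus-plane planning and per-voxel defocus-index arrays, a
    slab-wise tilt-series simulator with depth-dependent CTF, a Monte
    Carlo simulation of the signal attenuation caused by phase-flipping
    at erroneous defocus, Fourier shell correlation and local
    correlation metrics, and readers/writers for MRC2014 volumes, tilt
    angle lists and plain-text defocus tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
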