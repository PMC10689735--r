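Package: exmquant
Title: Quantification Toolkit for Expansion Microscopy Images
Version: 0.1.0
Authors@R:
    person("exmquant", "maintainers", email = "exmquant@example.org",
           role = c("aut", "cre"))
Description: Measurement and simulation tools for super-resolution
    quantification of expansion-microscopy data: nuclear-pore corner
    counting from thresholded point clouds with s-fold sector analysis,
    expansion-factor calibration against molecular rulers and measurement
    correction, nucleus cross-section (NCS) statistics from segmented
    masks, antibody linkage-error modelling, line and polar intensity
    profiling (FWHM, peak separation, angular offsets), FFT-based
    periodicity detection along ciliary structures, and seeded synthetic
    generators (NPC point clouds, periodic dot chains, ring images,
    nucleus masks, striped profiles) that provide ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
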