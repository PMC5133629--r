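Package: topomorph
Title: Time-Lapse Cell-Shape Morphometry and Alignment Analysis for
    Nanotopography Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how substrate nanotopography shapes stem-cell
    morphology over long time-lapse experiments. Provides a ground-truthed
    synthetic time-lapse generator (axial von Mises orientations, saturating
    spreading kinetics, ellipse rendering with PSF blur and noise), a
    transparent fluorescence segmentation stage, per-object shape metrics
    (area, contour perimeter, form-factor circularity, moment-equivalent and
    minimal enclosing ellipse axes, orientation), population alignment via
    summed 2D-FFT angular power spectra over [0, 180) degrees, F-test based
    shape-divergence times between culture conditions, and delta-delta-Ct
    relative quantification of qPCR panels with housekeeping normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
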