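Package: digibead
Title: Compartmentalization-Free Digital Bead Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying compartmentalization-free digital bead
    assays from static micrographs. Beads are located in a brightfield or
    darkfield localization channel with a gradient circular Hough detector,
    each bead's maximum fluorescence intensity is extracted, beads are
    classified "on"/"off" against a Gaussian blank threshold (mean + 2 SD),
    and the on-fraction is converted to the average number of analyte
    molecules per bead (AMB) by Poisson inversion, AMB = -ln(1 - f_on).
    Dose-response calibration uses a four-parameter logistic fit with the
    limit of detection defined at three blank standard deviations above the
    blank mean. A ground-truthed synthetic assay and micrograph generator
    reproduces the statistical structure the analysis assumes (Poisson
    molecule loading, bimodal bead intensities, frame-wise subsampling), so
    the whole pipeline is testable without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
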