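Package: slicethick
Title: Thickness Morphometry for Vibratome-Cut Tissue Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures the thickness of agarose-embedded tissue-slice
    cross-sections from calibrated microscopy images. A dark slice band on a
    bright field is segmented by automated thresholding, aligned so that its
    principal axis is vertical, and per-row foreground widths are converted
    into calibrated thickness estimates (mean, standard deviation,
    coefficient of variation with an irregularity flag). Slice-level records
    are aggregated into per-condition accuracy statistics -- the thickness
    error relative to the nominal vibratome step size -- with two-way
    analysis of variance, Tukey honest-significant-difference comparisons
    and compact letter displays. A synthetic cross-section generator with
    analytic ground truth supports end-to-end validation without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    car,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
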