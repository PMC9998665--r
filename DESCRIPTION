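Package: exoct
Title: Automatic Exophthalmometry from 2D Orbital CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic measurement of eye protrusion (exophthalmos) on
    2D orbital CT slices. Segments the eye globe with a small U-Net++
    convolutional network trained with a soft Dice loss, extracts the bony
    orbital rim by intensity thresholding, morphological opening and
    small-component removal, localizes the rim's most protruding points and
    the corneal apex, and reports the perpendicular distance from the apex to
    the line through the rim apexes in both axial and sagittal views.
    Includes a synthetic phantom generator with analytically known ground
    truth, segmentation overlap metrics (Dice, IoU, precision, recall), and
    inter-method agreement statistics (Lin's concordance correlation,
    two-way absolute-agreement intraclass correlation, Bland-Altman limits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    jsonlite,
    png,
    rlang,
    igraph,
    EBImage,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
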