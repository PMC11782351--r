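Package: vstain
Title: Label-Free Virtual Staining and Quantification for Plant Cell Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for label-free "virtual staining" of plant cell
    bright-field micrographs and for the downstream quantification such
    images support. Provides a seeded synthetic microscopy-scene generator
    with ground truth (pavement cells, cell files, chloroplast fields,
    live/dead cell crops), a residual channel attention UNet (RCA-UNet)
    for bright-field to fluorescence image regression, threshold overlap
    score (TOS) colocalization with logarithmic rescaling, Otsu and
    tolerance-based watershed segmentation with per-cell morphometrics
    (area, perimeter, circularity, solidity, aspect ratio), centroid
    tracking of organelle motion with speeds in micrometres per second,
    and gray-level co-occurrence (Haralick) texture features with a
    random-forest live/dead classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
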