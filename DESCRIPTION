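Package: chromamotion
Title: Chromatic ON/OFF Motion Vision Analysis for Drosophila UV-Green Displays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing chromatic motion-vision experiments in which
    UV and green stimuli are traded off against each other to locate
    isoluminance points of the ON- and OFF-motion pathways. Implements
    looming-disc and competing-edge stimulus generation on an angular grid
    with UV/green display calibration, zero-crossing isoluminance estimation
    from tethered-flight wingbeat recordings, a calcium-imaging pipeline
    (rigid alignment, flood-fill ROI segmentation, dF/F0, polarity-specific
    response metrics and responsiveness thresholds, ROI/fly/population
    isoluminance), a hexagonal-lattice Weber-contrast model of chromatic
    ON/OFF motion estimation in natural images, and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    nortest,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
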