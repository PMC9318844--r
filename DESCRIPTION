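Package: thermleak
Title: Detecting Underground Natural Gas Micro-Leakage from Canopy Thermal Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting underground natural-gas micro-leakage from
    infrared thermal images of vegetation canopies. Gas accumulating in the
    root zone stresses plants, raising canopy temperature in a quasi-circular
    footprint around the leak; the package classifies stressed versus control
    plots with a compact GoogLeNet-style convolutional network topped by
    bilinear pooling, localizes the stressed area with gradient-weighted class
    activation maps (Grad-CAM), adaptive-threshold segmentation and
    least-squares circle fitting, and provides the supporting analytics:
    a seeded synthetic thermal-scene simulator with known ground truth,
    marker-artifact cleaning, label-preserving augmentation, transfer
    learning, confusion-matrix metrics, canopy temperature cross-section
    statistics, concentration-temperature regression and inverse-distance
    contouring of point gas samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr
Config/testthat/edition: 3
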