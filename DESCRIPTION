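Package: burnmetry
Title: 2D Projection and 3D Surface Area Measurement of Wounds from Depth Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Measures wound size from LiDAR-style depth maps and segmentation
    masks. Pixels are unprojected to real-world coordinates with a pinhole
    camera model; wound size is reported both as the area of the wound contour
    projected onto its Newell best-fit plane (the "2D projection area") and as
    a grid-triangulated curved surface area built from Heron triangles (the
    "3D surface area"). An elliptical cross-section curvature model predicts
    how body-surface curvature inflates the 3D/2D area ratio, and a synthetic
    limb-phantom generator renders depth maps of circular templates wrapped on
    planes, cylinders, elliptical cylinders and spheres with analytically
    known ground-truth areas, supporting end-to-end validation and cohort
    simulations with tidy summaries and regression fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
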