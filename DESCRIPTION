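Package: pseudoDXA
Title: Simulated DXA Projections, Femoral-Neck Morphometry, and
    Sex-Specific aBMD-Strength Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates synthetic three-dimensional femoral-neck voxel
    volumes with sex-specific geometry, projects them into
    two-dimensional pseudoDXA density maps, computes DXA-style
    (area, BMC, aBMD, neck widths) and 3D morphometric (cross-sectional
    areas, second moments of area, compartment volumes) parameters, and
    runs the regression and ANCOVA procedures that expose how dividing
    bone mineral content by a bone-size measure creates sex-specific
    associations between areal BMD and whole-bone strength. Includes
    closed-form elliptical-annulus section properties, an
    idealized-geometry fit-and-predict analysis, Hounsfield-unit
    calibration, volume rotation and region-of-interest extraction,
    morphological cortical/trabecular partitioning, and a reproducible
    study pipeline with descriptive, elevation, and multivariable
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
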