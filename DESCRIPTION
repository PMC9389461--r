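Package: spheromigrate
Title: Quantification of Cell Recruitment and Migration Anisotropy in Biomaterials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the extent and spatial anisotropy of cell migration
    into porous biomaterials from spheroid-based invasion assays. From nucleus
    centroid positions (or segmentable grayscale projections of confocal
    stacks) and the cell-source geometry, the package computes per-nucleus
    migration distances, local cell-density maps on an overlapping circular
    ROI grid, isodensity profiles at configurable density thresholds, direct
    least-squares ellipse fits of those profiles, and the anisotropy ratios R
    (from paired 2D layer assays) and R* (from the 3D spheroid assay,
    corrected for the spheroid radius). A 2D anisotropic-diffusion reference
    simulation and a synthetic nucleus-cloud generator with known ground
    truth are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    mgcv,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
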