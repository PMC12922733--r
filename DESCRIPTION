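Package: pdmap
Title: Cell-Type-Resolved 3D Quantification of Plasmodesmata Pit Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps plasmodesmata pit-field fluorescence across plant roots in
    3D at cell-type and cell-interface resolution. Segments cells from a
    cell-wall stain channel by Gaussian smoothing and seeded 3D watershed,
    extracts smoothed cell-surface meshes and cell-cell interface patches
    with their areas, annotates radial cell layers and interface orientation
    classes in a root-axis cylindrical frame, projects the pit-field marker
    channel onto interfaces with a depth-compensated background trim, and
    computes per-interface Total Signal, Signal Density, sample-normalized
    percentages and Moran's I spatial autocorrelation, with group comparisons
    by Welch t-tests. Includes a synthetic-root image generator with analytic
    ground truth so the whole workflow is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    yaml,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
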