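Package: printdrr
Title: Simulated Radiographs of FDM 3D-Printed Parts from G-Code
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts fused-deposition-modeling (FDM) printer G-code into a
    binary voxel volume ("virtual printing") and computes digitally
    reconstructed radiographs (DRRs) of the virtual part at arbitrary
    projection angles, for parallel- and cone-beam geometries. Includes a
    lightweight slicer that generates hexagonal test specimens with grid,
    cubic, or gyroid infill at a chosen density, an exact Siddon-style
    ray-voxel projector reporting material path length per detector pixel,
    and an artifact analysis that sweeps the tilt angle between the central
    ray and the build direction to locate the projections of least and
    greatest infill artifact.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    graphics,
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
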