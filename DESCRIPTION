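Package: motionmesh
Title: Superpixel Optical-Flow Tracking and Dynamic-Mesh Statistics for
    Collective Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies single-cell and collective cellular motion in
    timelapse microscopy without segmenting or tracking individual cells.
    Frame-0 superpixels are propagated through time by averaging a dense
    Farneback optical-flow field over each superpixel footprint, giving
    long-time tracks for every image region. Graphs built over the tracks
    (a frozen frame-0 "MOSES" mesh, per-frame radius-neighbour graphs,
    kNN graphs) yield mesh strain curves, a mesh stability index, mesh and
    velocity order parameters, mean-squared-displacement exponents,
    spatial velocity correlation, normalized velocity cross-correlation,
    motion saliency maps and a boundary formation index. Additional tools
    detect gap closure between two migrating epithelial sheets, extract
    and describe the boundary line (shape, infiltration, intermixing,
    kymographs), embed videos into 2-D motion maps from normalized strain
    curve signatures, and cluster superpixel tracks by their local strain
    dynamics. A synthetic-video generator with scripted outcomes
    (coalescence, stable boundary, push-through) provides ground-truthed
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    mclust,
    minpack.lm,
    png,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
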