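Package: mcamtk
Title: Simulation and Image-Processing Pipeline for Multi-Camera Array Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with multi-camera array microscopes (MCAMs):
    grids of closely spaced micro-cameras whose partially overlapping fields
    of view are computationally combined into gigapixel-scale mosaics. The
    package provides thin-lens array geometry and resolution calculations, a
    ground-truthed scene simulator that renders per-camera raw framesets
    (fish-, worm- and bead-like organisms with defocus, vignetting and sensor
    noise), flat-field correction and bilinear demosaicing, phase-correlation
    stitching with a reusable calibration template, tiled object detection
    with cross-tile non-maximum suppression, stereoscopic depth estimation
    from adjacent-camera disparity, identity-preserving tracking with a
    triplet-loss embedder, and behavioral readouts (occupancy maps, tail and
    eye kinematics, optical-flow activity, segmentation-based counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
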