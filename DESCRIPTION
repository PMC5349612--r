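Package: rollmap
Title: Label-Free Adhesion Mapping of Rolling Cells by Rotation Tracking
    and Adhesion Footprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map the surface adhesion of cells undergoing rolling
    adhesion under shear flow. Reconstructs the rotation of individual
    rolling cells from intracellular scatterers in dark-field movies
    (segmentation, trajectory linking, arccos angle unfolding, cumulative
    angle and angular velocity), converts angle traces into dwell-time
    adhesion maps with periodicity analysis (2-pi stacking, normalized
    autocorrelation, patch-size estimation, polar export), and analyses
    fluorescent adhesion-footprint images (flat-field correction, tile
    stitching, 2D cross-correlation period detection, per-period averaging,
    contact geometry). Includes seeded simulators for synthetic rolling-cell
    movies, synthetic footprint tiles and a random-microvilli contact model,
    so every stage is testable against known ground truth, plus a
    parallel-plate flow-channel wall shear stress calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
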