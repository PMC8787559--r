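Package: nucleifuse
Title: Nuclei Segmentation Post-Processing, Fusion, Evaluation and Mask Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for annotation-efficient nuclei instance segmentation of
    fluorescence microscopy images. Converts instance label maps to the
    three-class (inner/contour/background) semantic representation with
    inverse-frequency class weights, reconstructs instances from semantic
    class-probability maps via seeded Voronoi assignment, fuses instance and
    semantic segmentation results with overlap rules, scores segmentations
    with the mutual-best-match IoU F1 curve, and simulates realistic nuclei
    mask images from fitted Gaussian count and Gumbel size distributions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
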