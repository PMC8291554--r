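Package: visor
Title: Oblique Light-Sheet Volumetric Imaging: Reconstruction, Cell
    Detection and Whole-Brain Activation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for volumetric imaging with synchronized on-the-fly
    scan and readout (VISoR): acquisition geometry arithmetic for
    45-degree oblique light-sheet imaging of moving cleared-tissue
    slices, a ground-truthed phantom and acquisition simulator, column
    deskew and correlation-based stitching, four-step serial-slice
    reconstruction (surface flattening, dense correspondences, global
    adjustment, moving-least-squares warping), progressive bilateral
    HDR tone mapping, difference-of-Gaussian/watershed cell detection
    with 3D linking and dual-channel colocalization, and region-level
    activation statistics (relative z-scores, coefficients of
    variation, Welch t-tests with FDR q-values).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
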