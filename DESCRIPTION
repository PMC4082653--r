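Package: retractx
Title: Brain Retraction Correction with an Extended Finite Element Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based correction of surgical brain retraction for image-guided
    neurosurgery. Tracks retractor blades from probe coordinates and sparse laser
    range scans (trimmed iterative-closest-point augmentation and coherent point
    drift nonrigid registration), converts the tracked surfaces into Dirichlet
    boundary conditions on a uniform hexahedral mesh, solves a linear elastic
    extended finite element (XFEM) system with Heaviside and crack-tip enrichment
    to represent the retraction-induced tissue discontinuity, and warps the
    pre-retraction image volume with a crack-aware back-interpolation to produce
    model-updated images. Includes a synthetic brain-phantom generator with
    embedded fiducial beads and an evaluation layer (bead forecast error,
    correction accuracy, modified Hausdorff distance on Canny edges).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
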