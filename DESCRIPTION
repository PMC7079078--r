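Package: plaquediff
Title: Longitudinal Coronary Plaque Thickness Comparison from Contour Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies local changes in coronary artery plaque thickness
    between a baseline and a follow-up acquisition. Lumen and vessel-wall
    cross-sectional contour stacks are modelled as subdivision surfaces
    refined from a shared hexagonal-ring coarse mesh, so that every surface
    vertex has a stable identity linking lumen to wall and baseline to
    follow-up. Centerlines derived from the lumen contours are registered
    with rigid coherent point drift, the follow-up coarse mesh is mapped
    into baseline coordinates, and per-vertex plaque thickness differences
    are computed, classified against a clinical threshold, and exported as
    colored meshes. A synthetic artery-tree generator produces
    baseline/follow-up pairs with known plaque edits for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    Matrix,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
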