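Package: subtalax
Title: Subtalar Joint Kinematics via Helical and Facet-Axis Decompositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body kinematics of the subtalar (talocalcaneal) joint from
    triangle meshes of the talus and calcaneus in multiple static postures.
    Implements the classical finite helical-axis decomposition of a rigid
    displacement and an alternative decomposition in which rotation occurs
    about an axis while translation follows an anatomically defined direction,
    namely the cylinder axis best fitting the posterior talar facet. Includes
    orthogonal-distance least-squares cylinder fitting, point-to-point
    iterative closest point registration of bone surfaces, an anatomical foot
    coordinate frame built from landmarks, a synthetic hindfoot phantom
    generator with known ground-truth motion, STL/PLY mesh input/output, and
    an end-to-end analysis pipeline producing per-foot kinematic reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
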