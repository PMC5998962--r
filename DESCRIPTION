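Package: laminae3d
Title: Detection of Cortical Laminar Surfaces in 3D Histological Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, surface-based detection of intracortical laminar
    surfaces (the layer I/II boundary and a mid-layer IV surface) from
    cell-body-stained 3D histological volumes paired with linked white and
    pial cortical surface meshes. Includes layer-preserving anisotropic
    volume smoothing with peak-count-based smoothing-level selection,
    staining-intensity profile extraction and simulated laminar density
    profiles, equivolumetric cortical depth, iterative surface refinement,
    curvature-depth morphometry with BIC model comparison, oblique
    2D-sectioning error analysis, validation statistics against manual
    delineations, and a synthetic folded-cortex phantom generator with
    known laminar ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
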