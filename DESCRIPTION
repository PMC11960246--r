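Package: cartmorph
Title: Knee Cartilage Morphometry: Statistical Shape Models, Defect Heat
    Maps and Local Radii of Curvature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for morphometric analysis of distal femoral cartilage
    surfaces aimed at focal knee resurfacing implant design. Builds a PCA
    statistical shape model from corresponded triangulated cartilage
    meshes (rigid and stiffness-relaxed non-rigid iterative closest point
    registration followed by generalised Procrustes alignment), samples
    artificial cartilage populations from the model, maps focal defect
    models onto the mean shape to produce per-vertex defect-location
    frequency heat maps, characterises defect size and aspect ratio, and
    measures local signed anteroposterior and mediolateral radii of
    curvature at probe points via least-squares cylinder and circle
    fitting. Includes a synthetic bicondylar cohort generator with
    closed-form curvature ground truth and analytic fixtures (sphere
    caps, cylinder patches, saddles, planar ellipses) so every stage can
    be validated without patient data. Reads and writes ASCII PLY, OBJ
    and STL surface meshes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
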