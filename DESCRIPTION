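Package: jointpose
Title: Anatomical and Joint Coordinate Systems for Archosaur Hindlimb Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional hindlimb joint poses from bone surface
    models and rigid-body transforms. Fits geometric primitives (spheres,
    cylinders, planes) to articular surface patches of triangulated bone
    meshes, constructs asymmetric anatomical coordinate systems (ACS) for the
    pelvis, femur, crus and pes via T-shaped principal vectors, builds
    Grood-Suntay-style joint coordinate systems (JCS), and decomposes relative
    bone motion into six degrees of freedom (flexion-extension,
    abduction-adduction and long-axis rotation as intrinsic Z-Y-X Tait-Bryan
    angles, plus translations along the fixed-ACS axes), with reference-pose
    assembly, a per-frame dynamic pedal coordinate system for unfused
    metatarsals, and gimbal-lock detection. Includes a synthetic-limb generator
    with exactly known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
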