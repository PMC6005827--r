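Package: hemovox
Title: Image-Based Hemodynamics on Voxel Grids with a Sharp-Interface
    Immersed Boundary Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Highly automated image-to-hemodynamics modelling for vascular
    structures such as intracranial aneurysms. A vessel/aneurysm lumen is
    segmented directly from a voxelized contrast volume by seeded 3D region
    growing, the wall is represented by a level-set function built from image
    intensity, and incompressible blood flow is simulated on the voxel
    Cartesian grid with a sharp-interface (ghost-fluid) immersed boundary
    method on a staggered grid. Post-processing computes wall pressure, wall
    shear stress and normalized hemodynamic metrics over a designated aneurysm
    region. A phantom generator supplies synthetic angiogram-like volumes with
    analytic ground truth (straight and curved tubes, sidewall aneurysms,
    disconnected vessels) so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    xml2
Config/testthat/edition: 3
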