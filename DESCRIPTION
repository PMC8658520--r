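Package: implantfem
Title: Voxel-Based Finite Element Analysis of Peri-Implant Bone Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Virtual dental implant-therapy simulation on heterogeneous
    mandibular bone. Generates synthetic mandibular-segment CT volumes (or
    imports DICOM/NIfTI scans), converts CT numbers to apparent bone density
    and a piecewise Young's modulus, performs virtual tooth extraction and
    parametric implant placement, meshes the labelled volume into 4-node
    tetrahedra, solves linear static elasticity under an oblique occlusal
    load, and summarises equivalent (von Mises) stress in the peri-implant
    bone across an implant diameter-by-length design grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
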