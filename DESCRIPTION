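Package: qpath
Title: Voxel Risk Maps and Tabular Q-Learning for Surgical Corridor Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing neurosurgical approach corridors on a
    segmented 3D brain volume. A labeled volume plus a per-segment risk
    table yields a per-voxel penalty field; hand-drawn straight pathways
    are voxelized as fixed-diameter cylinders and scored by summing voxel
    risks; and a tabular Q-learning planner over the voxel adjacency
    graph extracts minimum-penalty nonlinear corridors from a surface
    entry point to a deep target region. Includes a synthetic phantom
    generator, an exact Dijkstra oracle for validation, NRRD/NIfTI and
    CSV readers and writers, approach-comparison reports, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
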