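Package: CorticoPath
Title: Two-Stage Surgical Trajectory Planning on Labeled MR Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plans minimally harmful cortico-tumoral surgical trajectories on
    labeled 3D MR voxel volumes in two stages. Stage 1 enumerates every
    candidate entry window on the six volume faces, traces straight corridors
    to the tumor, scores them against a penalty catalog of critical anatomy
    (vessels, sinuses, white-matter tracts, eloquent cortex, deep nuclei),
    and reduces them to a short list through a staged funnel. Stage 2 builds
    a 26-neighbor voxel-node environment from the Stage-1 output and trains
    a tabular Q-learning agent to extract nonlinear paths that reach the
    tumor while avoiding penalized structures. Includes DICOM series and
    NIfTI volume handling, labelme-style polygon rasterization, a synthetic
    labeled-head phantom generator, and a value-iteration oracle for
    verifying trained policies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
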