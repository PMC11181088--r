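Package: poseRSA
Title: Representational Similarity Analysis of Human Body Pose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Parameterizes 3D human body poses as view-dependent 2D,
    view-dependent 3D, view-independent 3D, and viewpoint representations;
    builds model and control representational dissimilarity matrices (RDMs)
    and relates them to multi-voxel fMRI response patterns by standard and
    partial-correlation representational similarity analysis at searchlight
    and region-of-interest level, with cluster-based sign-flip permutation
    inference and Monte Carlo noise-ceiling estimation.  Ships a synthetic
    data generator (articulated poses under random viewpoints, COCO-style
    keypoint records, voxel responses with planted representational
    geometry) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
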