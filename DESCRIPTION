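Package: vishom
Title: Visual Homogeneity Analysis for Visual Search and Symmetry Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs perceptual spaces from oddball visual-search
    reaction times by multidimensional scaling, models responses to
    multi-item displays by multiple-object averaging, and fits a
    distance-to-center decision variable (visual homogeneity) whose
    correlations with response times have opposite signs for
    target-present (or asymmetric) versus target-absent (or symmetric)
    displays. Includes searchlight procedures relating local mean voxel
    activation to visual homogeneity and local neural dissimilarity to
    perceptual dissimilarity, and a synthetic-data generator with known
    ground truth for parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
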