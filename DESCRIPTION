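Package: cordmap
Title: Cerebro-Spinal Resting-State Somatotopy: Denoising, iCAPs,
    Winner-Take-All Mapping and Connectivity-Based Parcellation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional connectivity
    between the cervical spinal cord and the sensorimotor cortex. Provides a
    synthetic phantom generator with planted somatotopic coupling, quality
    control (framewise displacement, temporal SNR), a full nuisance model
    (RETROICOR cardiac/respiratory harmonics, CompCor CSF components, discrete
    cosine detrending, motion regressors) with orthogonal band-pass projection
    denoising and Gaussian smoothing, innovation-driven co-activation patterns
    (regularized hemodynamic deconvolution, significant innovation frames,
    polarity-folded K-means, consensus clustering), seed-to-voxel functional
    connectivity with Fisher z transform and winner-take-all somatotopic maps,
    and connectivity-based parcellation of the cord by average-linkage
    hierarchical clustering of functional-similarity profiles with Dice
    validation via maximum-weight label matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
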