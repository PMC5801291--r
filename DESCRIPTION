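Package: bayesppm
Title: Classical and Bayesian Second-Level Inference for Group fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Group-level (second-level) one-sample inference on fMRI
    contrast images, comparing classical mass-univariate t-tests with
    random-field-theory familywise-error control (voxelwise and
    cluster-extent) against empirical-Bayes posterior probability maps
    thresholded jointly on effect size and log posterior odds. Includes a
    synthetic contrast-image generator with planted activation blobs and
    spatially smooth between-subject noise, a noise-injection robustness
    harness (false-alarm and hit rates over replicates), and incremental
    sample-size sweeps with per-voxel statistic trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
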