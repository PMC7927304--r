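Package: intertract
Title: Interoception and White-Matter Microstructure Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying relationships between cardiac interoception and
    white-matter microstructure with diffusion-tensor imaging. Implements
    heartbeat-tracking accuracy, body-awareness and interoceptive
    trait-prediction-error scoring with the associated behavioral statistics
    (Welch tests, ANCOVA, false-discovery-rate correction); voxel-based
    fractional-anisotropy analysis with masked Gaussian smoothing, voxel-wise
    general linear models, effect sizes and Monte-Carlo cluster-wise
    correction; streamline tractography utilities including query-based bundle
    selection, probability/curvature/crossing-fiber filtering and probabilistic
    bundle atlases; and white-matter-to-gray-matter network lesion mapping.
    A seeded synthetic-data generator produces phantom orientation fields,
    fractional-anisotropy cohorts and heartbeat-tracking trials with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
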