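Package: loomsight
Title: Looming-Trajectory Stimuli and Collision-Sensitivity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates and analyses looming-stimulus experiments on
    collision-trajectory detection. Covers the full analysis chain:
    three-dimensional approach-trajectory geometry with world-to-screen
    projection and centre-of-mass alignment, Horn-Schunck optical-flow and
    luminance diagnostics, maximum-likelihood psychometric (cumulative
    normal) fitting with exact sign-flip permutation tests, pupillometric
    preprocessing with cluster-length permutation inference, voxel-grid
    cluster-mass permutation tests with small-volume correction,
    leave-one-subject-out and leave-one-run-out cross-validated
    region-of-interest readout, repeated-measures ANOVA with effect sizes,
    beta-series effective connectivity, and maximum-likelihood path-model
    search over an enumerated model space with parsimony-based selection.
    Seeded synthetic-data generators emulate every input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
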