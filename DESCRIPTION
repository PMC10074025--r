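Package: fedrf
Title: Federated Deep Regression Forests for Tabular Biomedical Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-silo horizontal federated learning for tabular regression
    problems such as anticancer drug-response prediction. Provides a
    feature-to-image embedding that arranges high-dimensional feature vectors
    on a pixel grid via multidimensional scaling with a constrained
    assignment (one feature per pixel), deep regression forests whose soft
    tree routing is driven by a small neural network and whose leaves carry
    Gaussian distributions updated by variational bounding, data-weighted
    federated averaging of network and leaf parameters with an optional
    personalized last layer, a Gelman-Rubin style heterogeneity diagnostic
    computed from per-client validation-loss trajectories, and a seeded
    synthetic drug-response data generator with random and drug-clustered
    client partitions for end-to-end simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
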