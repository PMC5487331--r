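Package: versatility
Title: Nodal Versatility of Community Affiliation in Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how ambiguously a stochastic community-detection
    algorithm assigns each node of a network to a community. An ensemble of
    partitions is condensed into an association matrix of co-assignment
    probabilities, from which per-node versatility is computed under a family
    of estimators; the canonical estimator (sine transform, community-size
    normalisation) is bounded by pi and is zero exactly when assignment is
    deterministic. Includes idealised model networks with closed-form
    oracles, a seeded Louvain resolution-parameter sweep that selects the
    resolution minimising global mean versatility, the participation
    coefficient for contrast, readers and writers for common graph formats,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
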