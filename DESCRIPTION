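Package: raynn
Title: Ray-Traced Spherical Neural Networks with Glial Occlusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and trains bio-inspired neural networks whose neurons and
    glial cells occupy positions inside a three-dimensional sphere. Connections
    are formed by ray tracing with line-of-sight occlusion by intervening
    cells, stored in a sparse weighted adjacency matrix, and trained with
    backpropagation through time using a five-parameter trainable activation
    function per neuron. Networks grow between datasets while preserving
    trained weights, supporting transfer learning across changing input
    dimensions. Includes closed-form results for cell collision probability
    and connection-length distributions, Monte-Carlo characterization sweeps,
    and a synthetic received-signal-strength localization data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
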