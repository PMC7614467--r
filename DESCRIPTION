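Package: pcgraph
Title: Predictive-Coding Networks on Arbitrary Directed Graph Topologies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference and learning by local prediction-error minimization on
    directed graphs of any topology. Each vertex carries a value node, a
    prediction formed from its in-neighbours, and a local error; value nodes
    relax by gradient descent on a quadratic energy and weights follow a local
    Hebbian-like update. A trained graph is queried by clamping (conditioning)
    or initializing subsets of vertices, so one model performs generation,
    reconstruction, denoising, classification and associative-memory retrieval
    without retraining. Includes declarative topology builders (layered,
    lateral, Erdos-Renyi neuron assemblies with top-k firing), a synthetic
    glyph-pattern generator, task runners with tidy metric output, model
    serialization, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
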