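Package: flockattn
Title: Attention-Limited Flocking in Complex Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Agent-based simulation of collective motion where each
    individual attends to only its k nearest objects, so that social
    neighbours and point-like danger sites compete for a limited number of
    attention slots. Implements the stochastic heading dynamics with
    informed individuals and danger-site repulsion on a periodic box,
    random and structured environment generators, model variants (direct
    detection, active signaling, Voronoi-restricted neighbourhoods), the
    order parameters and network observables that quantify the emergent
    coordination-responsiveness trade-off, and reproducible parameter
    sweeps with paired non-interacting controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
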