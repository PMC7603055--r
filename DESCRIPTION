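Package: somscape
Title: Self-Organizing Map Portraits and Gene-State Trajectories for
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Portrays single-cell transcriptomes as self-organizing map
    (SOM) metagene images, segments the resulting expression landscape
    into labeled modules, extracts gene-state differentiation
    trajectories as maximum-capacity paths on the module adjacency
    network and as topographic least-cost paths on difference
    portraits, orders cells along a diffusion pseudotime scaled from a
    root population, and projects RNA-velocity estimates onto the map
    as a two-dimensional vector field with attractors and basins.
    Includes a synthetic stem-to-tissue differentiation generator with
    known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    png,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
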