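Package: cephnet
Title: Correlation Network Analysis of Cephalometric Measurements
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes classical lateral-cephalometric measurements from named
    2D landmarks via a declarative recipe registry, builds absolute-Pearson
    correlation networks over the measurement variables with data-driven
    cutoffs, identifies clusters and cliques across nested cutoffs, and
    extracts the minimum spanning tree (Kruskal) of the 1 - |r| distance
    matrix. Includes a block-structured multivariate Gaussian generator that
    emulates the correlation structure of normal-occlusion cephalometric
    data, an end-to-end pipeline with GraphML/TSV/CSV/JSON artifacts, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
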