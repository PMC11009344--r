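Package: mdcnet
Title: Influential Nodes from Degree Disassortativity and Community Structure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies influential nodes in undirected networks by combining
    local degree disassortativity with community boundary structure.
    Implements the disassortativity-of-node score (DoN), which counts the
    neighbours a node dominates in degree, and the mDC influence metric,
    which blends DoN with a community-coefficient-weighted boundary
    popularity.  Ships re-implementations of classical and community-aware
    baseline centralities (degree, betweenness, reciprocal-distance
    closeness, modularity vitality, community hub-bridge, community-based
    mediator), an LFR-style benchmark graph generator with planted
    communities, targeted-attack robustness curves (largest connected
    subgraph size, network efficiency), discrete SIR immunization
    experiments, top-k ranking overlap, and edge-perturbation stability
    analysis, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
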