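Package: csntox
Title: Chemical Space Network Criticality Analysis for Toxicity Read-Across
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds chemical space networks (CSNs) from maximum common
    subgraph (MCS) Tanimoto similarities between small molecules, sweeps the
    similarity threshold against uniform Erdos-Renyi null ensembles to locate
    the percolation-like critical point (betweenness peak, giant-component
    onset, assortativity maximum), characterises molecular communities at
    criticality with Louvain detection and a Mood's median descriptor screen,
    and predicts binary toxicity labels with a similarity-weighted neighbour
    vote under repeated stratified hold-out cross-validation. Includes a
    synthetic scaffold-family generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
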