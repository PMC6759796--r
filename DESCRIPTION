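Package: netpharm
Title: Network Pharmacology and Non-Compartmental Pharmacokinetics for
    Multi-Component Herbal Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacokinetics-anchored network
    pharmacology: intersecting putative compound targets with disease target
    lists, building the bipartite component-target network, computing
    NetworkAnalyzer-convention topological metrics (degree, normalized
    betweenness, average shortest path length, closeness) per connected
    component, detecting dense clusters with an MCODE implementation
    (vertex weighting, seeded expansion, post-processing), filtering
    confidence-scored protein-protein interactions, hypergeometric
    over-representation analysis against GMT gene-set collections, and
    non-compartmental estimation of Cmax, Tmax, terminal half-life and AUC
    from plasma concentration-time profiles. Includes a synthetic-data
    generator with planted structure so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
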