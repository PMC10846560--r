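Package: netcrosstalk
Title: Disease Crosstalk Prioritization on Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based network propagation (NetShort, NetZcore, NetScore and
    their NetCombo combination) over protein-protein interaction networks,
    extraction of phenotype subnetworks (seeds, top-scoring nodes and linkers),
    pairwise overlap scoring between disease categories, merged global-network
    analysis with degree and betweenness centrality and a dual
    stress-included/excluded scoring scheme, and hypergeometric pathway
    over-representation. Includes a synthetic-interactome generator with
    planted disease modules and crosstalk bridges so the whole pipeline can be
    exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
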