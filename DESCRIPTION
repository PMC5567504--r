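Package: topophen
Title: Topological Phenotyping of Clinical Cohorts with Connectome Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers patient subgroups in clinical feature matrices with a
    Mapper-style topological data analysis pipeline (reference z-scoring
    against typically developing controls, Euclidean distances, L-infinity
    centrality lens, nerve graph, flare extraction and peripheral-subject
    selection) and validates them against resting-state functional
    connectomes: motion scrubbing, Pearson correlation networks, weighted
    degree/betweenness/PageRank centralities, Louvain modularity with
    NMI-based consensus over repeated runs, module-resolved functional
    connectivity density, and a group-comparison layer (ANOVA from raw data
    or printed summaries, ANCOVA, Benjamini-Hochberg FDR, Bonferroni
    post-hocs). A synthetic-data generator with known ground truth makes the
    whole pipeline testable without access to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
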