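Package: mwmm
Title: Maximum Weighted Merger Method for miRNA-mRNA Correlation-Inversion Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters miRNA-mRNA pairs whose expression correlation inverts sign
    between normal and tumor tissue. Implements six edge-weight formulas that
    combine tumor and normal correlation coefficients (including a data-driven
    integrated mean value weight), a top-n edge-accretion procedure for comparing
    the formulas, the maximum weighted merger method (MWMM) itself - iterated
    maximum-weight bipartite matching that grows one star graph per miRNA,
    followed by repeated maximum-weight general matching on a cross-weight
    auxiliary graph that merges clusters pairwise - plus per-cluster validity
    metrics (inner weight, outer weights, two density conditions), the adjusted
    Rand index for comparing clusterings, and a planted-cluster synthetic
    generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    igraph,
    generics,
    stats,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
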