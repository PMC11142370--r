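Package: episnet
Title: Comparative SNP Epistasis Networks Under Cartesian and XOR Interaction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares SNP-SNP interaction (epistasis) networks from
    pairwise regression scans of quantitative traits under two interaction
    encodings: the classical Cartesian (multiplicative) product and the
    exclusive-or (XOR) penetrance model. Edges are weighted by FDR-adjusted
    interaction p-values; an edge-weight threshold is selected by greedy
    modularity maximization over a fine threshold sweep. Networks are compared
    by positional-tolerance node and edge matching and by a directional
    community-similarity score summarised as a normalized area under the curve.
    Triangle motifs are enumerated and tested for three-way epistasis to
    prioritize higher-order interactions. A synthetic genotype/phenotype
    simulator with planted Cartesian and XOR architectures supports power and
    type-I-error studies and makes the full pipeline testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
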