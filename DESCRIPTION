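Package: tnwclust
Title: Clustering of Temporal Event Sequences by Temporal Needleman-Wunsch
    Alignment and Bootstrap Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns discrete temporal event sequences (symbols with
    inter-event durations, e.g. therapy switch histories of patients)
    pairwise with the temporal Needleman-Wunsch algorithm, converts the
    resulting similarity matrix into distances, clusters subjects by
    agglomerative hierarchical clustering, and selects and validates the
    number of clusters by bootstrap resampling using five
    partition-comparison indices (Rand, adjusted Rand, Fowlkes-Mallows,
    Jaccard, adjusted Wallace) and three per-cluster stability measures
    (Jaccard, recovery rate, Dice). Includes a continuous-time Markov
    chain simulator for generating labelled synthetic sequence datasets
    and transition-graph summaries of the final clusters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
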