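Package: vesselnet
Title: Directed Weighted Vessel-Traffic Networks for Marine Biosecurity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing inter-island tourist-vessel traffic as a
    directed weighted network for marine biosecurity planning. Builds
    trip-frequency networks from timetable records, tests for weighted
    small-world structure against a simulated random-network ensemble,
    ranks islands by invasion-risk indices (out-degree, out-strength,
    betweenness, out-closeness on inverted-weight distances), detects
    communities with a Leiden-style optimizer for directed weighted
    modularity together with a degree-preserving permutation test and
    per-community vulnerability metrics, and re-weights edges by a
    Gaussian sea-surface-temperature similarity kernel with seasonal
    Kruskal-Wallis/Dunn comparisons. Includes a synthetic archipelago
    generator so the full pipeline is testable without proprietary
    trip data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
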