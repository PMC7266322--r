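Package: axelgroup
Title: Axelrod Cultural Dissemination with Agreement Thresholds on a Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates Axelrod's model of cultural dissemination on a
    non-periodic square lattice, in the standard form and with an ordinal
    agreement-threshold interaction rule suited to Likert-type attitude data.
    Provides bipartite agent-attitude representations and their one-mode
    projections, opinion-based-group (non-spatial) cluster statistics,
    reproducible ensemble experiments over feature counts and thresholds,
    figure styles for lattices, bipartite graphs, projections and ensemble
    summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    grDevices,
    tools,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
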