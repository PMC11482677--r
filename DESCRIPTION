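Package: pollinet
Title: Eco-Evolutionary Dynamics, Collapse and Revival of Plant-Pollinator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates eco-evolutionary dynamics of bipartite mutualistic
    plant-pollinator networks in which species interact through matching
    quantitative traits with a saturating (type II) functional response, and
    mean phenotypes evolve under selection with fixed heritable variation.
    Provides the three experimental protocols used to study tipping points in
    such networks: collapse sweeps over the average mutualistic strength,
    hysteresis (restoration) sweeps from the collapsed state, and revival of
    collapsed networks by transiently forcing one or a few species. Includes
    structural network metrics (connectance, NODF nestedness, weighted
    nestedness, modularity, betweenness centrality), a nestedness-tunable
    synthetic network generator, synthetic visitation tables emulating field
    restoration surveys, indirect-effect summaries, and self-contained
    quasibinomial/least-squares regression stages for structure-recovery
    relationships.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    igraph,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
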