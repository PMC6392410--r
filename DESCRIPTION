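Package: hummnet
Title: Continental-Scale Analysis of Hummingbird-Plant Mutualistic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing binary bipartite mutualistic
    networks between hummingbird clades and the plant families they visit for
    nectar. Builds clade-by-family interaction matrices from species-level
    visitation records (with optional filtering of plants non-native to the
    New World), fits exponential, power-law and truncated power-law models to
    the cumulative degree distribution with AIC model selection, computes NODF
    nestedness under sorted or externally fixed (phylogenetic) node orders,
    tests statistics against equiprobable (ER), cell-probability (CE) and
    fixed-fixed (curveball) null ensembles with standardized effect sizes,
    detects modules by simulated-annealing maximisation of Newman-Girvan
    modularity with multi-run consensus membership and within/among-module
    (z, c) node roles, summarises clade-level biogeography and floral
    pollination syndromes, and fits binomial GLMs of multi-region occupancy on
    the center of diversification and clade with likelihood-ratio tests,
    Bonferroni-corrected pairwise contrasts and an overdispersion check. A
    synthetic-data generator with tunable nestedness and modular structure
    makes every stage reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    multcomp,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
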