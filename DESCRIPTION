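Package: grnoise
Title: Evolution of Gene-Specific Expression Noise in Gene Regulatory
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time evolutionary simulation of gene regulatory
    networks with heritable, gene-specific expression noise. Extends the
    Wagner gene network model with a per-gene intrinsic noise variance so
    that both the mean and the variability of expression are genetically
    encoded. Provides generators for weighted directed network topologies
    (Erdos-Renyi, Barabasi-Albert, Watts-Strogatz), a two-stage
    evolutionary engine (deterministic network establishment toward
    intermediate expression, then stochastic evolution of the noise
    genotype under stabilizing selection or neutrality), node- and
    graph-level network metrics with principal-component synthetic axes,
    and outcome statistics (expression variance, relative variance change,
    gene-level selective pressure and responsiveness, mutual information
    with Monte Carlo permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
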