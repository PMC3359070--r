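Package: lbasim
Title: Simulation Study of Long-Branch Artefacts in Maximum Likelihood
    Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how long-branch effects distort maximum
    likelihood phylogeny inference on multi-taxon trees. Simulates gap-free
    DNA alignments along 11-taxon model trees under the Jukes-Cantor model
    with continuous gamma-distributed site rates and a proportion of
    invariant sites; infers trees by maximum likelihood (Felsenstein
    pruning with a discrete-gamma plus invariant-sites mixture, neighbor
    joining start, NNI hill climbing); classifies wrong topologies into
    class I (symplesiomorphy), class II (signal erosion) and class III
    (Felsenstein zone) long-branch artefacts; and orchestrates replicated
    branch-length grids, returning tidy per-replicate records and per-cell
    summaries of reconstruction success and rate-parameter estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
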