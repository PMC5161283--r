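Package: hedgesim
Title: Stochastic Bistable Switches and the Evolution of Bet-Hedging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models phenotypic bet-hedging as a stochastic genotype-phenotype
    map implemented by bistable chemical reaction network (CRN) switches.
    Provides a discrete (jump-chain) Gillespie simulator for mass-action CRNs
    with absorbing states, a library of canonical switches (direct-competition
    DC/DCx/DCy, approximate-majority AM, and the redundant DCdup) with exact
    switching-probability solvers (gambler's-ruin closed forms and a sparse
    Markov-chain absorption solve), quasispecies population dynamics for a
    two-phenotype population, multitype branching-process fixation
    probabilities for invading mutants, strong-selection weak-mutation
    simulations of the evolutionary loss of bet-hedging with closed-form
    expected loss times, and a birth-death treatment simulator for exploring
    treatment holidays against bet-hedging-driven drug resistance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
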