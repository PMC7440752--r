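Package: pgmcmc
Title: Parsimony-Guided Tree Proposals for Bayesian Phylogenetic MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian phylogenetic Markov chain Monte Carlo over unrooted
    binary trees whose centerpiece is a family of parsimony-guided subtree
    pruning-and-regrafting (pSPR) and tree bisection-and-reconnection (pTBR)
    proposals with exact Hastings corrections, alongside the standard
    stochastic NNI and extending SPR/TBR moves. Includes Fitch parsimony with
    incremental scoring of all regraft and reconnection candidates,
    Felsenstein pruning likelihoods under JC69, K80 and GTR with discrete
    gamma rate variation, uniform topology and compound gamma-Dirichlet
    branch-length priors, Metropolis coupling, a sequence simulator for
    verification experiments (including a long-branch-attraction fixture),
    and convergence diagnostics based on split frequencies (ASDSF).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    yaml
Config/testthat/edition: 3
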