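Package: crntrans
Title: Analytic Stationary Distributions of Reaction Networks via Network Translation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Derives analytic stationary distributions of the chemical master
    equation for stochastic biochemical reaction networks by structure
    transformation. A network is translated -- reactions sharing a
    stoichiometric vector are merged and reactions are shifted -- into a
    weakly reversible deficiency-zero form, the translated propensities are
    factorized as kappa * theta(n) * omega(n - nu), a complex balanced
    equilibrium of the associated deterministic mass-action system is solved,
    and the product-form stationary distribution pi(n) = M * c^n / theta(n)
    is assembled on the irreducible state space. Includes exact Gillespie
    simulation for validation, quasi-steady-state reduction of multi-timescale
    networks, and an Erdos-Renyi random-network deficiency survey.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
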