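Package: crndecomp
Title: Stationary Distributions of Stochastic Reaction Networks via Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stochastic chemical reaction networks viewed as
    continuous-time Markov chains: structural analysis (linkage classes,
    deficiency, reversibility, conservation laws), state-space exploration
    (irreducible components, essentiality), exact stationary distributions by
    master-equation solves on finite components, product-form stationary
    distributions (Poisson forms at points of complex balance, two-species
    exchange motifs under mass-action or Hill-type kinetics), and assembly of
    stationary distributions of joined networks from reaction-disjoint
    decompositions whose parts have matching product-form functions.
    Includes a Gillespie stochastic simulation algorithm for empirical
    validation and a plain-text reaction-list format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    boot,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
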