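Package: redqueen
Title: Stochastic and Deterministic Models of Host-Parasite Red Queen Dynamics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based stochastic models of host-parasite co-evolution
    under matching-allele infection. Implements five model variants spanning
    evolutionary game theory and theoretical ecology (Moran-type Evo+,
    pairwise-comparison Evo, a rate-balanced Hybrid, and Lotka-Volterra-type
    EcoEvo models with and without intraspecific host competition), their
    discrete-time counterparts with exact mean genotype-extinction times by
    sparse first-passage linear algebra, an exact Gillespie stochastic
    simulation engine, the deterministic limits (replicator, adjusted
    replicator, Lotka-Volterra), and the extinction-time, population-size
    sweep, diversity-decay and mutation-revival experiments used to compare
    them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Matrix,
    optparse,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
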