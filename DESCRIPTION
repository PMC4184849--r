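Package: mkmorph
Title: Bayesian Mk and Parsimony Estimation of Phylogeny from Discrete
    Morphological Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference machinery for comparing Bayesian
    estimation under the binary Mk model against equally-weighted parsimony
    for discrete morphological characters. Includes a binary-character
    simulator with gamma rate heterogeneity along user-supplied or generated
    trees, ascertainment-bias corrections for variable-only and
    parsimony-informative-only character sampling (Mkv and Mk-parsinf),
    a Metropolis-Hastings MCMC sampler over topologies, branch lengths and
    gamma shape, a Fitch parsimony engine with random-addition starting
    trees and TBR branch swapping, Robinson-Foulds topological error
    scoring, and an experiment layer that reruns the full factorial design
    (rate grid x filtration x missing data x method) at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
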