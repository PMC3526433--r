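Package: phynetml
Title: Maximum Likelihood Inference of Reticulate Evolutionary Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers phylogenetic networks (reticulate evolutionary
    histories with inheritance probabilities) from multi-gene DNA sequence
    alignments by maximum likelihood. Provides a rooted binary network data
    structure with displayed-tree enumeration, Felsenstein-pruning tree
    likelihoods under the Kimura (1980) substitution model, the mixture
    network likelihood over displayed trees, a forward-selection heuristic
    search over networks of increasing reticulation number, AIC/BIC model
    selection with the derived log-likelihood-improvement thresholds, and a
    seeded simulation and evaluation harness for horizontal gene transfer
    scenarios (species trees, SPR-derived gene trees with recorded truth,
    K80 sequence simulation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    dplyr
Config/testthat/edition: 3
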