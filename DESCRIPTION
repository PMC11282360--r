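Package: mastr
Title: Mixtures Across Sites and Trees for Phylogenetic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference under the MAST (mixtures across
    sites and trees) model, in which the likelihood of each alignment site is
    a weighted sum over a user-supplied set of bifurcating tree topologies,
    each carrying its own branch lengths and (optionally linked) GTR
    substitution model, base frequencies, and discrete-gamma rate
    heterogeneity. Parameters are estimated by an expectation-maximization
    workflow with quasi-Newton refinement of linked parameter blocks, from a
    parsimony-based initialization. Includes sequence simulators for tree
    mixtures, random subtree-prune-and-regraft neighbor topologies, and a
    four-taxon structured coalescent with a single introgression pulse, plus
    experiment harnesses for parameter-recovery and BIC model-selection
    studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
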