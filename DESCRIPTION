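Package: treelen
Title: Treelength Optimization for Generalized Tree Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic tree estimation from unaligned nucleotide
    sequences under treelength (parsimony-with-indels) criteria. Implements
    affine-gap pairwise edit distances, fixed-tree treelength scoring with
    lifted, direct-optimization and exact solvers, implied multiple sequence
    alignments, random p-ECR tree perturbations, a candidate-pool search that
    returns the shortest tree found, tree and alignment error metrics
    (missing branch rate, SP-FN, majority consensus), and a sequence
    evolution simulator with indels that records the true alignment and
    per-branch event counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp,
    Biostrings,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
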