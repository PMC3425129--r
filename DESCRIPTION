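Package: rabrep
Title: Profile-HMM Subfamily Classification and Ancestral Repertoire
    Inference for Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying protein sequences into subfamilies with
    profile hidden Markov models, calibrating E-value confidence cut-offs from
    member and decoy score distributions, estimating classifier sensitivity and
    positive predictive rate by resampling, refining a subfamily partition by
    iterated search and similarity-graph clustering, building distance-based
    neighbor-joining phylogenies with bootstrap support, and reconstructing
    ancestral gene repertoires by Dollo parsimony under alternative rootings of
    the eukaryotic tree. Ships a synthetic sequence-family generator and a
    curated presence/absence compendium for the Rab GTPase family so that the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
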