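Package: smtphylo
Title: Gene-Family Phylogenetics of Animal Sterol Methyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for reconstructing the evolutionary
    history of the animal 24-C sterol methyltransferase (smt) gene family.
    Provides phylogeny-aware contamination vetting of transcriptome-derived
    homologs, conserved-domain screening and redundancy removal,
    gene-tree/species-tree reconciliation under duplication-loss parsimony
    with rearrangement of poorly supported branches, Dollo-parsimony
    mapping of gene loss, and a fossil-calibrated uncorrelated-lognormal
    relaxed molecular clock (LG+Gamma amino-acid likelihood, Yule tree
    prior, Metropolis-Hastings MCMC). A synthetic-data module simulates
    gene families evolving inside dated species trees with duplication,
    loss, rate heterogeneity and cross-phylum contamination, giving
    ground truth for every inference stage. A small chemistry helper
    reproduces the carbon-number and trimethylsilyl fragment-ion
    arithmetic used to interpret sterol mass spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
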