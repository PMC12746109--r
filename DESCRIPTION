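Package: phenomine
Title: Literature-Mined Microbial Phenotype Networks and Genotype Association
Version: 0.1.0
Authors@R:
    person("Phenomine", "Developers", email = "phenomine@example.org",
           role = c("aut", "cre"))
Description: Toolkit for the computational stages around literature mining of
    bacterial phenotypes: corpus preparation (filtering, BIO span encoding,
    stratified splits, class-imbalance augmentation), strict and partial
    span-matching evaluation of named-entity and relation predictions,
    strain-name normalization against a reference catalog by two-stage
    Levenshtein matching, construction and scale-free analysis of the typed
    directed phenotype network, triad-based inference of trophic strain-strain
    interactions (cross-feeding, competition, inhibition, resistance),
    gradient-boosted gene-phenotype association on Pfam copy-number features
    with GO enrichment, benchmarking against curated phenotype references, and
    seeded synthetic-data generators so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
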