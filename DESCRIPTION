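Package: fitpaths
Title: Evolutionary Accessibility of Mutational Pathways on Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the evolutionary accessibility of
    mutational pathways on binary-genotype fitness landscapes. Provides
    samplers for four classical landscape ensembles (House of Cards, Rough
    Mount Fuji, LK/NK, and holey/percolation landscapes), exact counting of
    selectively accessible shortest paths by depth-first backtracking,
    closed-form expectations for path numbers and single-path accessibility
    probabilities, and a subgraph-analysis pipeline for empirical
    genotype-fitness tables of the Aspergillus niger type (viable-subgraph
    counting, two-parameter lethality-model estimation, Poisson
    missing-genotype statistics, and fitness resampling), together with a
    synthetic-data generator that emulates such eight-locus data sets with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
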