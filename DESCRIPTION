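Package: colonynet
Title: Screen-to-Network Analysis of Yeast Colony-Morphology Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates a genome-wide deletion-screen phenotype readout with a
    confidence-weighted physical interaction network for Saccharomyces
    cerevisiae. Edges (protein-protein, phosphorylation and protein-DNA
    interactions) are weighted by a naive Bayesian classifier trained on the
    experimental techniques supporting each interaction; screen hits are
    overlaid on the network; protein complexes, pathways and Gene Ontology
    terms are tested for association with the hit set by cumulative
    hypergeometric statistics with multiple-testing correction; redundant
    enriched terms are grouped by chance-corrected (kappa) agreement of their
    gene sets; and wild-type versus mutant expression contrasts are tested
    with an empirical-Bayes moderated t-statistic. A synthetic-data module
    generates interactomes, ontologies, screens and expression matrices with
    planted ground truth so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
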