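Package: herbwalk
Title: Herb and Ingredient Prioritization by Biased Random Walks on a
    Multiscale Interactome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Network-pharmacology pipeline that prioritizes medicinal herbs
    and their ingredients for a disease by propagating their protein targets
    over a multiscale interactome of proteins and biological functions.
    Implements biased random walk with restart diffusion profiles over the
    three network layers (protein-protein, protein-function annotation,
    function hierarchy), correlation scoring of entity profiles against a
    disease profile, hypergeometric overlap and fold-enrichment statistics,
    core-target identification, gene-set over-representation analysis with
    combined scores, and extraction of top-k mechanism subnetworks linking
    an ingredient to a disease. Includes seeded generators for synthetic
    interactomes and herb catalogs with planted effective herbs so the full
    pipeline is testable without access to proprietary databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
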