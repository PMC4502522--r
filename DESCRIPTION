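Package: OrthoUnits
Title: Cross-Species Ortholog Interaction Networks and Molecular
    Process Units for Microbial Communities
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-centric data structures for two-species microbial
    communities, ortholog assignment by global protein alignment,
    cross-species interaction imputation by orthology (interolog
    transfer), COG-level aggregate networks, MCODE density-based graph
    segmentation into molecular process units, and assembly of a
    molecular process model with inter-unit dependencies and
    species-specific gene overlays. Includes a deterministic synthetic
    community generator with planted orthologs and planted dense
    interaction modules so that every pipeline stage can be validated
    offline against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Network, GraphAndNetwork, Clustering, Alignment,
    FunctionalGenomics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'align.R'
    'community.R'
    'cog.R'
    'network.R'
    'mcode.R'
    'pipeline.R'
    'processModel.R'
    'synth.R'
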