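Package: PolyphasicTaxa
Title: Polyphasic Delineation of Novel Bacterial Taxa and Culture-Collection
    Analytics for Gut Microbiomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning bacterial isolate sequences and genome
    assemblies into taxonomic and ecological conclusions. Implements pairwise
    16S rRNA gene comparison (alignment identity, Kimura 2-parameter distance,
    greedy centroid clustering at the 98.7% species boundary), whole-genome
    metrics (fragment-based average nucleotide identity, percentage of
    conserved proteins, MinHash genome distance, a digital DNA-DNA
    hybridization estimate, assembly quality statistics), a rule engine that
    combines these metrics with phylogenetic and phenotypic evidence into
    known-species / new-species / new-genus / new-family calls, equally
    weighted multi-study prevalence statistics with accumulation curves,
    cross-collection overlap of novel-taxon inventories, and nonredundant
    protein catalog construction with catalog-versus-catalog coverage.
    Ships a synthetic-data module that generates genome pairs, 16S pairs,
    proteome pairs and multi-study abundance tables with known ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, Classification, Sequencing
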