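Package: daquscope
Title: Microbial Community Analysis of Solid-State Fermentation Starters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the microbial communities of solid-state
    liquor fermentation starters (Daqu) from 16S OTU tables and metagenome
    gene catalogs. Implements OTU-table screening, cumulative sum scaling
    (CSS) normalization, rarefaction and alpha diversity, core-microbiome
    prevalence calling, group Venn partitioning, leave-one-out
    cross-validation stability selection of marker OTUs with shadow-feature
    all-relevant selection and random forests, filter-cascade lowest common
    ancestor (LCA) taxonomic annotation of gene catalogs, EC-based
    functional and per-enzyme taxon profiling, permutation statistics
    (PERMANOVA, Mantel) and rank statistics (Spearman, Wilcoxon) with
    Benjamini-Hochberg adjustment, and seeded synthetic-data generators
    with ground-truth registries so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
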