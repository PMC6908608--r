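Package: repertoire
Title: Metabolic Repertoire Analysis for Bacterial Isolate Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of the metabolic repertoire of
    bacterial isolate collections, such as host-associated microbiota
    culture collections. Provides flux balance and flux variability
    analysis on small to mid-size metabolic models, parsimonious
    gap-filling, carbon-source utilizability and byproduct screens,
    pairwise community growth simulation with ecological-interaction
    classification, a well-mixed dynamic-FBA co-culture simulator with
    extracellular enzyme species, homology-based pathway presence calls,
    metabolic-versus-phylogenetic similarity analysis with bootstrap
    clustering, BIOLOG phenotype-microarray fold-change analysis,
    adaptive-strategy (C/S/R) scoring, and trait-phenotype association
    with permutation tests. Ships seeded synthetic-data generators with
    planted ground truth so every stage is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    xml2,
    mclust,
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'model_io.R'
    'pathways.R'
    'diversity.R'
    'biolog.R'
    'lp.R'
    'fba.R'
    'community.R'
    'dfba.R'
    'stats.R'
    'uast.R'
    'pipeline.R'
    'synthetic.R'
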