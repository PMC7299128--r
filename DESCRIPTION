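Package: sporoshift
Title: Cross-Species Comparison of Sporophyte Developmental Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing time-course gene expression across two related
    species sharing a staged developmental programme, built around the moss
    sporophyte (four developmental stages, gametophyte reference samples).
    Provides negative-binomial differential expression to define preferentially
    sporophyte-expressed genes, classification of genes as homologous or
    species-specific from orthogroup tables and filtered protein alignment
    hits, stage-level PCA and Spearman expression-divergence matrices, fuzzy
    c-means clustering of temporal profiles with cross-species projection of
    one-to-one orthologs, condensation of clusters into early/mid/late major
    phases, detection of heterochronic shifts between species, parent-child
    Gene Ontology enrichment, and a seeded two-species count simulator with
    planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
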