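Package: PhosphoCons
Title: Conservation Analysis and Cross-Species Propagation of Phosphosites
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores the evolutionary conservation of reference-proteome
    phosphosites (Ser/Thr/Tyr) across configurable eukaryotic species groups
    from reference-anchored multiple sequence alignments, applying the
    Ser/Thr substitution-tolerance rule. Clusters conservation-pattern
    vectors and assigns descriptive High/Medium labels, computes
    hypergeometric term enrichment with Benjamini-Hochberg adjustment and
    domain fold enrichment, relates phosphosite conservation to kinase
    orthologue conservation, and propagates phosphosites to target species
    using the site plus adjacent (+1) residue conservation rule, with
    validation statistics against evidence tables. Includes a deterministic
    synthetic-data generator that plants conservation archetypes, term
    enrichments and evidence so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Proteomics, Phylogenetics, SequenceMatching, Clustering
RoxygenNote: 7.3.3
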