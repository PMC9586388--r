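Package: pepgraph
Title: Bipartite Peptide-Protein Graphs for Protein Inference and
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs and characterizes bipartite peptide-protein graphs
    from in silico tryptic digestion of protein sequence databases and from
    quantitative peptide-level tables. Proteins with identical peptide sets
    and peptides with identical protein sets are collapsed into nodes, the
    graph is decomposed into connected components, and components are grouped
    into node-type-preserving isomorphism classes via colored canonical
    labeling. Aggregated structural metrics (graph size distributions,
    unique/shared peptide breakdowns, isoform peptide cross-tabulations)
    quantify how difficult protein inference and quantification are for a
    given database and data set. A synthetic-data generator plants known
    graph motifs in artificial proteomes so every pipeline stage can be
    validated against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
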