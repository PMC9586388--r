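#!/usr/bin/env Rscript
# Database-level bipartite graphs: digest the simulated FASTA, collapse,
# decompose into components, classify isomorphism classes, and sweep the
# minimum peptide length (5/6/7/9) to show its effect on graph structure.
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(pepgraph))

db <- read_fasta("results/data/synthetic_db.fasta")
cfg <- digest_config(min_len = 7L, max_missed = 0L)

res <- run_fasta_level(db, cfg, out_dir = "results/database_level")
cat("\n-- database level (min_len 7) --\n")
print(res$summary)
cat("\n10 largest isomorphism classes:\n")
print(utils::head(res$classes[, c("count", "protein_nodes",
                                  "peptide_nodes",
                                  "unique_peptide_nodes",
                                  "shared_peptide_nodes", "edges")], 10))

sweep <- length_sweep(db, min_lens = c(5L, 6L, 7L, 9L), max_missed = 0L)
utils::write.table(sweep, "results/database_level/length_sweep.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\n-- minimum peptide length sweep --\n")
print(sweep[, c("min_len", "peptide_sequences", "peptide_nodes", "graphs",
                "graphs_one_protein", "isomorphism_classes",
                "largest_protein_nodes")])
cat("\nPlanted blocks are at least 7 residues, so minima of 5-7 are",
    "identical here;\nat 9 the shorter blocks disappear, losing peptide",
    "nodes and unique anchors.\nOn real proteomes, with their many short",
    "shared peptides, the same sweep\ndecomposes the largest graph",
    "dramatically.\n")

dist <- node_count_distributions(res$components)
for (metric in names(dist)) {
  utils::write.table(
    data.frame(bin = names(dist[[metric]]),
               proportion = as.numeric(dist[[metric]])),
    file.path("results/database_level",
              paste0("distribution_", metric, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("node-count distributions written to results/database_level/\n")
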