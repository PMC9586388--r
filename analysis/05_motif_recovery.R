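#!/usr/bin/env Rscript
# Validation analyses on planted structure: exact recovery of pure-motif
# databases, and the analytic detection model -- an M component survives
# intact on the quantitative level iff all three of its peptide nodes are
# detected, i.e. with probability d^3.

suppressPackageStartupMessages(library(pepgraph))

cfg <- digest_config(min_len = 7L, max_missed = 0L)

cat("-- pure-motif recovery --\n")
sigs <- list(smallest = c(1L, 1L), M = c(2L, 3L), N = c(2L, 2L),
             W = c(3L, 2L))
rows <- lapply(names(sigs), function(motif) {
  gen <- generate_database(
    synth_spec(n_components = 50L, motif_mix = stats::setNames(1, motif),
               seed = 20260928L), cfg)
  res <- run_fasta_level(gen$db, cfg, verbose = FALSE)
  data.frame(motif = motif, planted = 50L, classes = nrow(res$classes),
             recovered = res$classes$count[1L],
             protein_nodes = res$classes$protein_nodes[1L],
             peptide_nodes = res$classes$peptide_nodes[1L])
})
rec <- do.call(rbind, rows)
print(rec)
utils::write.table(rec, "results/motif_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("\n-- intact-M Monte Carlo at detection probability 0.8 --\n")
spmc <- synth_spec(n_components = 2000L, motif_mix = c(M = 1),
                   n_states = 2L, detection_prob = 0.8, missing_prob = 0,
                   seed = 20260929L)
gen <- generate_database(spmc, cfg)
tb <- generate_quant_table(gen$db, spmc, cfg)
cr <- compute_ratios(tb, "S1", "S2")
comps <- components_from_map(
  suppressMessages(map_quant_peptides(cr$valid_peptides, gen$db)))
sig <- vapply(comps, function(cp)
  paste(length(cp$protein_nodes), length(cp$peptide_nodes)), character(1))
intact <- sum(sig == "2 3") / spmc$n_components
se <- sqrt(0.8^3 * (1 - 0.8^3) / spmc$n_components)
cat(sprintf("observed intact fraction: %.4f; analytic d^3 = %.4f (SE %.4f)\n",
            intact, 0.8^3, se))
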