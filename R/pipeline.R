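# run a pipeline stage with the stage name prefixed to any error
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Database-level pipeline: FASTA to summary and class table
#'
#' Reads (or takes) a protein database, digests it in silico, builds the
#' collapsed bipartite graph, decomposes it into components, groups them
#' into type-preserving isomorphism classes and summarizes the run.
#' Stage counts are logged via \code{message()}; errors carry the name of
#' the failing stage.
#'
#' @param fasta path to a FASTA file, or a \code{protein_db} directly.
#' @param config a [digest_config()].
#' @param decoy_prefix passed to [read_fasta()].
#' @param include_decoys include decoy entries in the digest (default
#'   FALSE; assembled databases normally contain none).
#' @param out_dir if non-NULL, summary (JSON + TSV), class table and
#'   node/edge lists are written there.
#' @param verbose log stage counts (default TRUE).
#' @return list with \code{db}, \code{map}, \code{components},
#'   \code{classes}, \code{summary}.
#' @export
run_fasta_level <- function(fasta, config = digest_config(),
                            decoy_prefix = "DECOY_", include_decoys = FALSE,
                            out_dir = NULL, verbose = TRUE) {
  db <- stage("fasta_io", {
    if (inherits(fasta, "protein_db")) fasta
    else read_fasta(fasta, decoy_prefix = decoy_prefix)
  })
  say <- function(...) if (verbose) message(...)
  say("fasta_io: ", nrow(db), " entries")
  map <- stage("digestion", digest_database(db, config, include_decoys))
  say("digestion: ", length(map$entries), " peptides, ",
      length(map$excluded_accessions), " accessions excluded")
  components <- stage("graph_builder", components_from_map(map))
  say("graph_builder: ", length(components), " components")
  classes <- stage("isomorphism", classify_components(components))
  say("isomorphism: ", nrow(classes), " classes")
  summary <- stage("characterize",
                   summarize_dataset(components, classes, map))
  res <- list(db = db, map = map, components = components,
              classes = classes, summary = summary)
  if (!is.null(out_dir)) write_run_outputs(res, out_dir, level = "fasta")
  res
}

#' Quantitative-level pipeline: peptide table to pooled summary
#'
#' Preprocesses a quantitative peptide table (decoy and length filtering,
#' zero-to-missing, optional PTM summation), then for every pairwise
#' state comparison keeps only the peptides with a valid ratio, maps them
#' onto the database by substring matching, and builds that comparison's
#' collapsed components. Components from all comparisons are pooled as a
#' multiset and classified and summarized jointly.
#'
#' @param fasta path to a FASTA file or a \code{protein_db}.
#' @param table a \code{quant_table}.
#' @param config a [digest_config()] (supplies the length filter).
#' @param min_valid minimum non-missing replicates per state for a valid
#'   aggregated intensity (default 2, the triplicate rule).
#' @param decoy_prefix passed to [read_fasta()].
#' @param out_dir optional output directory.
#' @param verbose log stage counts.
#' @return list with \code{db}, \code{table} (preprocessed),
#'   \code{comparisons}, \code{ratios} (list of
#'   \code{comparison_ratios}), \code{per_comparison} (list of component
#'   lists), \code{components} (pooled), \code{classes}, \code{summary}.
#' @export
run_quant_level <- function(fasta, table, config = digest_config(),
                            min_valid = 2L, decoy_prefix = "DECOY_",
                            out_dir = NULL, verbose = TRUE) {
  db <- stage("fasta_io", {
    if (inherits(fasta, "protein_db")) fasta
    else read_fasta(fasta, decoy_prefix = decoy_prefix)
  })
  say <- function(...) if (verbose) message(...)
  n0 <- length(table$peptide)
  table <- stage("quant_processing", {
    tb <- filter_quant_peptides(table, config)
    if (!is.null(tb$modification)) tb <- aggregate_ptm_rows(tb)
    tb
  })
  say("quant_processing: ", length(table$peptide), " of ", n0,
      " rows kept after filtering")
  comparisons <- stage("quant_processing",
                       state_comparisons(table$design$state))
  if (nrow(comparisons) == 0L) stop("quant_processing: need >= 2 states")
  ratios <- list(); per_comparison <- list()
  for (i in seq_len(nrow(comparisons))) {
    cr <- stage("quant_processing",
                compute_ratios(table, comparisons$state_a[i],
                               comparisons$state_b[i], min_valid))
    cmp_map <- stage("quant_processing",
                     suppressMessages(
                       map_quant_peptides(cr$valid_peptides, db)))
    comps <- stage("graph_builder", components_from_map(cmp_map))
    lab <- paste0(comparisons$state_a[i], "_vs_", comparisons$state_b[i])
    ratios[[lab]] <- cr
    per_comparison[[lab]] <- comps
    say(lab, ": ", length(cr$valid_peptides), " valid peptides, ",
        length(comps), " components")
  }
  pooled <- do.call(c, unname(per_comparison))
  classes <- stage("isomorphism", classify_components(pooled))
  summary <- stage("characterize", summarize_dataset(pooled, classes))
  # distinct (not pooled-multiset) accession / peptide counts
  summary$protein_accessions <- length(unique(unlist(
    lapply(per_comparison, function(cs) unlist(
      lapply(cs, function(cp) unlist(cp$protein_nodes)))))))
  summary$peptide_sequences <- length(unique(unlist(
    lapply(ratios, function(r) r$valid_peptides))))
  res <- list(db = db, table = table, comparisons = comparisons,
              ratios = ratios, per_comparison = per_comparison,
              components = pooled, classes = classes, summary = summary)
  if (!is.null(out_dir)) write_run_outputs(res, out_dir, level = "quant")
  res
}

#' Summaries across a sweep of minimum peptide lengths
#'
#' Re-runs the database-level pipeline at several minimum peptide
#' lengths and stacks the one-row summaries (the standard way to judge
#' which minimum length decomposes the largest graph far enough).
#'
#' @param fasta path or \code{protein_db}.
#' @param min_lens minimum lengths to evaluate (default 5, 6, 7, 9).
#' @param max_len,max_missed remaining digestion settings.
#' @param ... passed to [run_fasta_level()].
#' @return data frame, one row per minimum length.
#' @export
length_sweep <- function(fasta, min_lens = c(5L, 6L, 7L, 9L),
                         max_len = 50L, max_missed = 2L, ...) {
  rows <- lapply(min_lens, function(ml) {
    res <- run_fasta_level(
      fasta, digest_config(min_len = ml, max_len = max_len,
                           max_missed = max_missed),
      verbose = FALSE, ...)
    cbind(min_len = ml, summary_row(res$summary))
  })
  do.call(rbind, rows)
}

# write the standard artifact set for a pipeline run
write_run_outputs <- function(res, out_dir, level) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, paste0(level, "_", f))
  jsonlite::write_json(lapply(unclass(res$summary), unname),
                       p("summary.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(summary_row(res$summary), p("summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_class_table(res$classes, p("classes.tsv"))
  write_component_tables(res$components, p("nodes.tsv"), p("edges.tsv"))
  manifest <- list(level = level,
                   graphs = res$summary$graphs,
                   classes = res$summary$isomorphism_classes,
                   files = basename(c(p("summary.json"), p("summary.tsv"),
                                      p("classes.tsv"), p("nodes.tsv"),
                                      p("edges.tsv"))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
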