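#' Aggregate summary of one graph-construction run
#'
#' The standard per-run overview: accession/sequence counts, collapsed
#' node and edge counts, number of components ("graphs"), number with a
#' single protein node, number of isomorphism classes, and the sizes of
#' the largest and second largest graph in terms of protein nodes (ties
#' broken like the deterministic component order). Edge counts are at the
#' collapsed level.
#'
#' @param components list of \code{bip_component} (deterministically
#'   ordered, as from [connected_components()]).
#' @param classes optional \code{iso_classes} for the same components
#'   (computed on the fly if missing).
#' @param map optional \code{pep_map}; if supplied, accession and peptide
#'   counts come from its included set, otherwise from the component
#'   members (equal by conservation).
#' @return named list of class \code{dataset_summary}.
#' @export
summarize_dataset <- function(components, classes = NULL, map = NULL) {
  if (is.null(classes)) classes <- classify_components(components)
  np <- vapply(components, function(cp) length(cp$protein_nodes), 1L)
  nq <- vapply(components, function(cp) length(cp$peptide_nodes), 1L)
  ne <- vapply(components, function(cp) nrow(cp$edges), 1L)
  n_acc <- if (!is.null(map)) length(map$included_accessions) else
    sum(vapply(components, function(cp)
      sum(lengths(cp$protein_nodes)), 1L))
  n_pep <- if (!is.null(map)) length(map$entries) else
    sum(vapply(components, function(cp)
      sum(lengths(cp$peptide_nodes)), 1L))
  triple <- function(i) {
    if (is.na(i)) c(protein_nodes = 0L, peptide_nodes = 0L, edges = 0L)
    else c(protein_nodes = np[i], peptide_nodes = nq[i], edges = ne[i])
  }
  o <- order(-np, -nq)
  structure(list(
    protein_accessions = n_acc,
    protein_nodes = sum(np),
    peptide_sequences = n_pep,
    peptide_nodes = sum(nq),
    edges = sum(ne),
    graphs = length(components),
    graphs_one_protein = sum(np == 1L),
    isomorphism_classes = nrow(classes),
    largest_graph = triple(if (length(o) >= 1L) o[1L] else NA),
    second_largest_graph = triple(if (length(o) >= 2L) o[2L] else NA)
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("dataset_summary\n")
  for (f in c("protein_accessions", "protein_nodes", "peptide_sequences",
              "peptide_nodes", "edges", "graphs", "graphs_one_protein",
              "isomorphism_classes")) {
    cat(sprintf("  %-22s %s\n", f, format(x[[f]], big.mark = ",")))
  }
  cat(sprintf("  largest graph          %d / %d / %d (prot/pep/edges)\n",
              x$largest_graph[1L], x$largest_graph[2L], x$largest_graph[3L]))
  cat(sprintf("  second largest graph   %d / %d / %d\n",
              x$second_largest_graph[1L], x$second_largest_graph[2L],
              x$second_largest_graph[3L]))
  invisible(x)
}

#' Flatten a dataset summary to a one-row data frame
#'
#' @param summary a \code{dataset_summary}.
#' @return one-row data frame (largest/second-largest triples unpacked).
#' @export
summary_row <- function(summary) {
  stopifnot(inherits(summary, "dataset_summary"))
  data.frame(
    protein_accessions = summary$protein_accessions,
    protein_nodes = summary$protein_nodes,
    peptide_sequences = summary$peptide_sequences,
    peptide_nodes = summary$peptide_nodes,
    edges = summary$edges,
    graphs = summary$graphs,
    graphs_one_protein = summary$graphs_one_protein,
    isomorphism_classes = summary$isomorphism_classes,
    largest_protein_nodes = summary$largest_graph[["protein_nodes"]],
    largest_peptide_nodes = summary$largest_graph[["peptide_nodes"]],
    largest_edges = summary$largest_graph[["edges"]],
    second_protein_nodes = summary$second_largest_graph[["protein_nodes"]],
    second_peptide_nodes = summary$second_largest_graph[["peptide_nodes"]],
    second_edges = summary$second_largest_graph[["edges"]])
}

#' Distributions of per-component node counts
#'
#' For each of protein nodes, peptide nodes, unique peptide nodes and
#' shared peptide nodes: the proportion of components with each exact
#' count 0..cap-1 plus a pooled "cap+" bin (default label "10+"),
#' summing to 1.
#'
#' @param components non-empty list of \code{bip_component}.
#' @param cap counts of \code{cap} and above are pooled (default 10).
#' @return named list of four proportion vectors with bin labels
#'   \code{"0"}, ..., \code{"<cap-1>"}, \code{"<cap>+"}.
#' @export
node_count_distributions <- function(components, cap = 10L) {
  stopifnot(length(components) >= 1L, cap >= 1L)
  counts <- list(
    protein_nodes = vapply(components, function(cp)
      length(cp$protein_nodes), 1L),
    peptide_nodes = vapply(components, function(cp)
      length(cp$peptide_nodes), 1L),
    unique_peptide_nodes = vapply(components, function(cp)
      sum(cp$is_unique), 1L),
    shared_peptide_nodes = vapply(components, function(cp)
      sum(!cp$is_unique), 1L))
  lapply(counts, function(x) {
    binned <- pmin(x, cap)
    tab <- tabulate(binned + 1L, nbins = cap + 1L) / length(x)
    names(tab) <- c(as.character(0:(cap - 1L)), paste0(cap, "+"))
    tab
  })
}

#' Uniqueness breakdown over peptide nodes, protein nodes and graphs
#'
#' Percentages of unique vs shared peptide nodes over all peptide nodes;
#' of protein nodes adjacent to only unique / both / only shared peptide
#' nodes over all protein nodes; and of components containing at least
#' one protein node without any unique peptide node (the hard case for
#' inference and quantification).
#'
#' @param components non-empty list of \code{bip_component}.
#' @return named list of class \code{uniqueness_breakdown} (all values
#'   percentages).
#' @export
uniqueness_breakdown <- function(components) {
  stopifnot(length(components) >= 1L)
  n_uni <- 0L; n_sha <- 0L
  p_only_uni <- 0L; p_both <- 0L; p_only_sha <- 0L
  graphs_lacking <- 0L
  for (cp in components) {
    n_uni <- n_uni + sum(cp$is_unique)
    n_sha <- n_sha + sum(!cp$is_unique)
    has_uni <- has_sha <- logical(length(cp$protein_nodes))
    if (nrow(cp$edges)) {
      uniq_e <- cp$is_unique[cp$edges[, "peptide"]]
      has_uni[unique(cp$edges[uniq_e, "protein"])] <- TRUE
      has_sha[unique(cp$edges[!uniq_e, "protein"])] <- TRUE
    }
    p_only_uni <- p_only_uni + sum(has_uni & !has_sha)
    p_both <- p_both + sum(has_uni & has_sha)
    p_only_sha <- p_only_sha + sum(!has_uni & has_sha)
    if (any(!has_uni)) graphs_lacking <- graphs_lacking + 1L
  }
  n_pep <- n_uni + n_sha
  n_prot <- p_only_uni + p_both + p_only_sha
  structure(list(
    peptide_nodes_unique_pct = 100 * n_uni / n_pep,
    peptide_nodes_shared_pct = 100 * n_sha / n_pep,
    protein_nodes_only_unique_pct = 100 * p_only_uni / n_prot,
    protein_nodes_both_pct = 100 * p_both / n_prot,
    protein_nodes_only_shared_pct = 100 * p_only_sha / n_prot,
    graphs_with_node_lacking_unique_pct =
      100 * graphs_lacking / length(components)
  ), class = "uniqueness_breakdown")
}

#' Cross-tabulate peptide uniqueness with and without isoforms
#'
#' Every peptide of the with-isoforms digest is classified at accession
#' level (unlike the node-level uniqueness used elsewhere): unique (one
#' accession), isoform-unique (two or more accessions all sharing one base
#' accession, i.e. shared only between a canonical sequence and its
#' isoforms) or shared (at least two distinct base accessions). This is
#' crossed with the peptide's status in the canonical-only digest: unique,
#' shared, or not existing there.
#'
#' @param map_canonical \code{pep_map} from the canonical-only database.
#' @param map_iso \code{pep_map} from the database including isoforms;
#'   both must stem from the same [digest_config()].
#' @return 4 x 4 integer matrix (rows: unique, isoform_unique, shared,
#'   sum; columns: unique, shared, not_existing, sum) of class
#'   \code{isoform_crosstab}.
#' @export
isoform_crosstab <- function(map_canonical, map_iso) {
  stopifnot(inherits(map_canonical, "pep_map"), inherits(map_iso, "pep_map"))
  if (!identical(unclass(map_canonical$config), unclass(map_iso$config))) {
    stop("isoform_crosstab: the two maps use different digestion settings")
  }
  iso_status <- vapply(map_iso$entries, function(acc) {
    if (length(acc) == 1L) return("unique")
    if (length(unique(base_accession(acc))) == 1L) return("isoform_unique")
    "shared"
  }, character(1))
  can_n <- lengths(map_canonical$entries)[names(map_iso$entries)]
  can_status <- ifelse(is.na(can_n), "not_existing",
                       ifelse(can_n == 1L, "unique", "shared"))
  tab <- table(factor(iso_status,
                      levels = c("unique", "isoform_unique", "shared")),
               factor(can_status,
                      levels = c("unique", "shared", "not_existing")))
  m <- matrix(as.integer(tab), 3L, 3L,
              dimnames = list(c("unique", "isoform_unique", "shared"),
                              c("unique", "shared", "not_existing")))
  m <- rbind(m, sum = colSums(m))
  m <- cbind(m, sum = rowSums(m))
  structure(m, class = c("isoform_crosstab", class(m)))
}

#' Write the isoform cross-tabulation as TSV
#'
#' @param crosstab an \code{isoform_crosstab}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_crosstab <- function(crosstab, path) {
  df <- data.frame(with_isoforms = rownames(crosstab),
                   unclass(crosstab), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
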