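#' Canonical key of a component under type-preserving isomorphism
#'
#' Two components receive the same key if and only if there is a bijection
#' of their nodes that maps edges onto edges and preserves the node type
#' (protein vs peptide). Node types enter the BLISS canonical labeling as
#' vertex colors, so an M-shaped and a W-shaped graph -- isomorphic as
#' plain graphs -- get different keys. Member multiplicities inside nodes
#' (how many accessions or sequences a node groups) are ignored.
#'
#' @param component a \code{bip_component}.
#' @return character scalar of class \code{canonical_key}: node counts,
#'   the color vector in canonical order, and the sorted canonical edge
#'   list.
#' @export
canonical_form <- function(component) {
  stopifnot(inherits(component, "bip_component"))
  np <- length(component$protein_nodes)
  nq <- length(component$peptide_nodes)
  if (nrow(component$edges)) {
    ep <- component$edges[, "protein"]; eq <- component$edges[, "peptide"]
    if (any(ep < 1L | ep > np) || any(eq < 1L | eq > nq)) {
      stop("component violates the bipartite invariant")
    }
  }
  ig <- igraph::make_empty_graph(n = np + nq, directed = FALSE)
  if (nrow(component$edges)) {
    ig <- igraph::add_edges(ig, rbind(component$edges[, "protein"],
                                      component$edges[, "peptide"] + np))
  }
  colors <- c(rep(0L, np), rep(1L, nq))
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  cg <- igraph::permute(ig, perm)
  el <- igraph::as_edgelist(cg, names = FALSE)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  ccol <- integer(np + nq)
  ccol[perm] <- colors
  key <- paste0("n", np + nq,
                "|c", paste(ccol, collapse = ""),
                "|e", paste(el[, 1L], el[, 2L], sep = "-", collapse = ","))
  structure(key, class = "canonical_key")
}

#' Exhaustive type-preserving isomorphism test (validation oracle)
#'
#' Decides isomorphism by brute force: after cheap invariant pre-checks
#' (node counts per type, edge count), it enumerates every permutation of
#' the protein nodes and, for each, compares the column-sorted permuted
#' incidence against the other graph's column-sorted incidence (sorting
#' columns is equivalent to trying every peptide-node permutation).
#' Deliberately independent of [canonical_form()].
#'
#' @param g,h \code{bip_component} objects with at most 12 nodes each.
#' @return logical scalar.
#' @export
brute_force_isomorphic <- function(g, h) {
  ng <- length(g$protein_nodes) + length(g$peptide_nodes)
  nh <- length(h$protein_nodes) + length(h$peptide_nodes)
  if (ng > 12L || nh > 12L) {
    stop("brute_force_isomorphic: size limit of 12 nodes exceeded")
  }
  np <- length(g$protein_nodes); nq <- length(g$peptide_nodes)
  if (np != length(h$protein_nodes) || nq != length(h$peptide_nodes) ||
      nrow(g$edges) != nrow(h$edges)) {
    return(FALSE)
  }
  inc <- function(cp) {
    m <- matrix(FALSE, length(cp$protein_nodes), length(cp$peptide_nodes))
    m[cp$edges] <- TRUE
    m
  }
  col_key <- function(m) {
    sort(apply(m, 2L, function(cl) paste(as.integer(cl), collapse = "")))
  }
  a <- inc(g); b <- inc(h)
  target <- col_key(b)
  for (p in all_permutations(np)) {
    if (identical(col_key(a[p, , drop = FALSE]), target)) return(TRUE)
  }
  FALSE
}

# all permutations of 1..n as a list (n <= ~7 in practice)
all_permutations <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, seq_len(n)[-i][p])))
  }
  out
}

#' Group components into isomorphism classes
#'
#' Iterates over the components, computes each one's canonical key, and
#' adds the component to the matching class, opening a new class when no
#' key matches. The representative of a class is the first component
#' encountered in the input (deterministic component) order. Classes are
#' reported in descending count order; ties are broken by ascending size
#' signature (protein nodes, peptide nodes, unique peptide nodes, shared
#' peptide nodes, edges), then by key.
#'
#' @param components list of \code{bip_component} (pooled across
#'   comparisons where applicable).
#' @return data frame of class \code{iso_classes} with columns \code{key},
#'   \code{count}, \code{protein_nodes}, \code{peptide_nodes},
#'   \code{unique_peptide_nodes}, \code{shared_peptide_nodes},
#'   \code{edges}, \code{representative} (index into \code{components});
#'   the representatives themselves are in
#'   \code{attr(, "representatives")}.
#' @export
classify_components <- function(components) {
  empty <- data.frame(key = character(0), count = integer(0),
                      protein_nodes = integer(0), peptide_nodes = integer(0),
                      unique_peptide_nodes = integer(0),
                      shared_peptide_nodes = integer(0), edges = integer(0),
                      representative = integer(0), stringsAsFactors = FALSE)
  if (length(components) == 0L) {
    class(empty) <- c("iso_classes", "data.frame")
    attr(empty, "representatives") <- list()
    return(empty)
  }
  keys <- vapply(components, function(cp) unclass(canonical_form(cp)),
                 character(1))
  uk <- unique(keys)
  cls <- match(keys, uk)
  rep_idx <- match(seq_along(uk), cls)
  sig <- t(vapply(components[rep_idx], size_signature, numeric(5)))
  df <- data.frame(key = uk, count = tabulate(cls, nbins = length(uk)),
                   protein_nodes = as.integer(sig[, 1L]),
                   peptide_nodes = as.integer(sig[, 2L]),
                   unique_peptide_nodes = as.integer(sig[, 3L]),
                   shared_peptide_nodes = as.integer(sig[, 4L]),
                   edges = as.integer(sig[, 5L]),
                   representative = rep_idx, stringsAsFactors = FALSE)
  o <- order(-df$count, df$protein_nodes, df$peptide_nodes,
             df$unique_peptide_nodes, df$shared_peptide_nodes, df$edges,
             df$key)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("iso_classes", "data.frame")
  attr(df, "representatives") <- components[df$representative]
  df
}

#' Size signature of a component
#'
#' @param component a \code{bip_component}.
#' @return numeric vector: protein nodes, peptide nodes, unique peptide
#'   nodes, shared peptide nodes, edges.
#' @export
size_signature <- function(component) {
  cl <- classify_peptide_nodes(component)
  c(protein_nodes = length(component$protein_nodes),
    peptide_nodes = length(component$peptide_nodes),
    unique_peptide_nodes = cl$n_unique,
    shared_peptide_nodes = cl$n_shared,
    edges = nrow(component$edges))
}

#' Write an isomorphism class table as TSV
#'
#' Columns: rank, count, percentage of all components, the size
#' signature, and a short key hash for cross-referencing.
#'
#' @param classes an \code{iso_classes} data frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_class_table <- function(classes, path) {
  stopifnot(inherits(classes, "iso_classes"))
  total <- sum(classes$count)
  df <- data.frame(
    rank = seq_len(nrow(classes)),
    count = classes$count,
    percentage = if (total > 0) 100 * classes$count / total else numeric(0),
    protein_nodes = classes$protein_nodes,
    peptide_nodes = classes$peptide_nodes,
    unique_peptide_nodes = classes$unique_peptide_nodes,
    shared_peptide_nodes = classes$shared_peptide_nodes,
    edges = classes$edges,
    key_hash = substr(vapply(classes$key, function(k)
      paste(format(sum(utf8ToInt(k) * seq_len(nchar(k))), scientific = FALSE)),
      character(1)), 1L, 12L),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
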