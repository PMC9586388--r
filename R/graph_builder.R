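#' Binary peptide x protein incidence matrix
#'
#' The uncollapsed biadjacency: rows are peptide sequences, columns are
#' included protein accessions, entry 1 iff the peptide belongs to the
#' protein. Stored sparse.
#'
#' @param map a \code{pep_map}.
#' @return A sparse logical \code{Matrix} with dimnames
#'   (peptides, accessions); 0 x 0 for an empty map.
#' @export
build_biadjacency <- function(map) {
  stopifnot(inherits(map, "pep_map"))
  peptides <- names(map$entries)
  accessions <- map$included_accessions
  if (length(peptides) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(0L, 0L)))
  }
  i <- rep.int(seq_along(peptides), lengths(map$entries))
  j <- match(unlist(map$entries, use.names = FALSE), accessions)
  if (anyNA(j)) stop("map entries reference accessions not in included set")
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(peptides), length(accessions)),
                       dimnames = list(peptides, accessions))
}

# row/column index pairs of the nonzero entries, for sparse or base matrices
incidence_triplets <- function(incidence) {
  if (inherits(incidence, "Matrix")) {
    m <- methods::as(incidence, "TsparseMatrix")
    list(i = m@i + 1L, j = m@j + 1L,
         dn = dimnames(incidence), dim = dim(incidence))
  } else {
    w <- which(incidence != 0, arr.ind = TRUE)
    list(i = as.integer(w[, 1L]), j = as.integer(w[, 2L]),
         dn = dimnames(incidence), dim = dim(incidence))
  }
}

#' Collapse indistinguishable proteins and peptides into nodes
#'
#' Proteins with identical peptide sets are indistinguishable by their
#' peptides and are merged into a single protein node (a protein group);
#' peptide sequences belonging to exactly the same set of protein nodes are
#' then merged into a single peptide node. One pass of each kind reaches a
#' fixed point (verified on construction): no two protein nodes share a
#' peptide-node neighborhood and no two peptide nodes share a protein-node
#' neighborhood.
#'
#' @param incidence binary incidence matrix from [build_biadjacency()]
#'   (peptides in rows, accessions in columns, dimnames required unless
#'   empty).
#' @return An object of class \code{bip_graph}: list with
#'   \code{protein_nodes} (list of accession sets), \code{peptide_nodes}
#'   (list of sequence sets) and \code{edges} (integer matrix, columns
#'   \code{protein}, \code{peptide}).
#' @export
collapse_nodes <- function(incidence) {
  tr <- incidence_triplets(incidence)
  if (length(tr$i) == 0L) {
    return(new_bip_graph(list(), list(),
                         cbind(protein = integer(0), peptide = integer(0))))
  }
  peptides <- tr$dn[[1L]]; accessions <- tr$dn[[2L]]

  # proteins first: group accessions by identical peptide-row support
  pep_by_acc <- split(tr$i, factor(tr$j, levels = seq_len(tr$dim[2L])))
  acc_key <- vapply(pep_by_acc, function(p) paste(sort(p), collapse = ","),
                    character(1))
  covered <- lengths(pep_by_acc) > 0L  # accessions with >=1 peptide
  pgroup_of_acc <- match(acc_key, unique(acc_key[covered]))

  # then peptides: group rows by identical protein-node support
  pnode_by_pep <- lapply(
    split(pgroup_of_acc[tr$j], factor(tr$i, levels = seq_len(tr$dim[1L]))),
    function(g) sort(unique(g)))
  pep_key <- vapply(pnode_by_pep, paste, character(1), collapse = ",")
  qgroup_of_pep <- match(pep_key, unique(pep_key))

  protein_nodes <- lapply(
    split(accessions[covered], pgroup_of_acc[covered]), sort)
  peptide_nodes <- lapply(split(peptides, qgroup_of_pep), sort)
  edges <- unique(cbind(protein = pgroup_of_acc[tr$j],
                        peptide = qgroup_of_pep[tr$i]))

  g <- new_bip_graph(unname(protein_nodes), unname(peptide_nodes), edges)
  stopifnot(collapse_is_fixed_point(g))
  canonical_order_bip_graph(g)
}

new_bip_graph <- function(protein_nodes, peptide_nodes, edges) {
  structure(list(protein_nodes = protein_nodes,
                 peptide_nodes = peptide_nodes,
                 edges = edges),
            class = "bip_graph")
}

# no two protein nodes with equal peptide-node neighborhoods and vice versa
collapse_is_fixed_point <- function(g) {
  nb <- function(idx, by, n) {
    sets <- split(idx, factor(by, levels = seq_len(n)))
    keys <- vapply(sets, function(s) paste(sort(unique(s)), collapse = ","),
                   character(1))
    !anyDuplicated(keys)
  }
  np <- length(g$protein_nodes); nq <- length(g$peptide_nodes)
  (np == 0L || nb(g$edges[, "peptide"], g$edges[, "protein"], np)) &&
    (nq == 0L || nb(g$edges[, "protein"], g$edges[, "peptide"], nq))
}

# deterministic node order: by smallest member label; edges sorted
canonical_order_bip_graph <- function(g) {
  po <- order(vapply(g$protein_nodes, min, character(1)))
  qo <- order(vapply(g$peptide_nodes, min, character(1)))
  edges <- cbind(protein = match(g$edges[, "protein"], po),
                 peptide = match(g$edges[, "peptide"], qo))
  edges <- edges[order(edges[, "protein"], edges[, "peptide"]), ,
                 drop = FALSE]
  new_bip_graph(g$protein_nodes[po], g$peptide_nodes[qo], edges)
}

#' @export
print.bip_graph <- function(x, ...) {
  cat("bip_graph:", length(x$protein_nodes), "protein nodes,",
      length(x$peptide_nodes), "peptide nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Expand collapsed edges back to the member-level incidence
#'
#' Inverse check of the collapsing step: every (protein node, peptide
#' node) edge expands to all member (accession, peptide) pairs.
#'
#' @param graph a \code{bip_graph} or \code{bip_component}.
#' @return data frame with columns \code{peptide}, \code{accession},
#'   sorted.
#' @export
expand_edges <- function(graph) {
  out <- lapply(seq_len(nrow(graph$edges)), function(e) {
    expand.grid(
      peptide = graph$peptide_nodes[[graph$edges[e, "peptide"]]],
      accession = graph$protein_nodes[[graph$edges[e, "protein"]]],
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(out, list(data.frame(peptide = character(0),
                                              accession = character(0)))))
  df[order(df$peptide, df$accession), , drop = FALSE]
}

#' Decompose a collapsed graph into connected components
#'
#' Components are returned in a deterministic order: descending protein
#' node count, ties broken by descending peptide node count, then by the
#' lexicographically smallest member accession.
#'
#' @param graph a \code{bip_graph} from [collapse_nodes()].
#' @return list of \code{bip_component} objects (same shape as
#'   \code{bip_graph}, plus \code{is_unique} per peptide node).
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "bip_graph"))
  np <- length(graph$protein_nodes); nq <- length(graph$peptide_nodes)
  if (np + nq == 0L) return(list())
  ig <- igraph::make_empty_graph(n = np + nq, directed = FALSE)
  if (nrow(graph$edges)) {
    ig <- igraph::add_edges(ig, rbind(graph$edges[, "protein"],
                                      graph$edges[, "peptide"] + np))
  }
  memb <- igraph::components(ig)$membership
  comps <- lapply(unique(memb), function(cid) {
    pin <- which(memb[seq_len(np)] == cid)
    qin <- which(memb[np + seq_len(nq)] == cid)
    keep <- graph$edges[, "protein"] %in% pin
    edges <- cbind(protein = match(graph$edges[keep, "protein"], pin),
                   peptide = match(graph$edges[keep, "peptide"], qin))
    new_bip_component(graph$protein_nodes[pin], graph$peptide_nodes[qin],
                      edges)
  })
  first_acc <- vapply(comps, function(cp)
    min(vapply(cp$protein_nodes, min, character(1))), character(1))
  o <- order(-vapply(comps, function(cp) length(cp$protein_nodes), 1L),
             -vapply(comps, function(cp) length(cp$peptide_nodes), 1L),
             first_acc)
  comps[o]
}

new_bip_component <- function(protein_nodes, peptide_nodes, edges) {
  g <- canonical_order_bip_graph(
    new_bip_graph(protein_nodes, peptide_nodes, edges))
  deg <- tabulate(g$edges[, "peptide"], nbins = length(g$peptide_nodes))
  g$is_unique <- deg == 1L
  class(g) <- c("bip_component", "bip_graph")
  g
}

#' Label peptide nodes of a component as unique or shared
#'
#' A peptide node is unique if it is adjacent to exactly one protein node
#' (which may itself group several indistinguishable accessions) and
#' shared if adjacent to at least two.
#'
#' @param component a \code{bip_component}.
#' @return list with \code{is_unique} (logical per peptide node),
#'   \code{n_unique} and \code{n_shared}.
#' @export
classify_peptide_nodes <- function(component) {
  stopifnot(inherits(component, "bip_component"))
  list(is_unique = component$is_unique,
       n_unique = sum(component$is_unique),
       n_shared = sum(!component$is_unique))
}

#' Build collapsed components straight from a peptide-protein map
#'
#' Convenience composition of [build_biadjacency()], [collapse_nodes()]
#' and [connected_components()].
#'
#' @param map a \code{pep_map}.
#' @return list of \code{bip_component}.
#' @export
components_from_map <- function(map) {
  connected_components(collapse_nodes(build_biadjacency(map)))
}

#' Convert a component to an igraph object
#'
#' Protein nodes come first, typed \code{"protein"}; vertex attributes
#' carry the member accessions/sequences and peptide-node uniqueness.
#'
#' @param component a \code{bip_component}.
#' @return an \code{igraph} graph with a logical \code{type} attribute
#'   (TRUE = peptide), as igraph expects for bipartite graphs.
#' @export
component_igraph <- function(component) {
  np <- length(component$protein_nodes)
  nq <- length(component$peptide_nodes)
  ig <- igraph::make_empty_graph(n = np + nq, directed = FALSE)
  if (nrow(component$edges)) {
    ig <- igraph::add_edges(ig, rbind(component$edges[, "protein"],
                                      component$edges[, "peptide"] + np))
  }
  igraph::V(ig)$type <- c(rep(FALSE, np), rep(TRUE, nq))
  igraph::V(ig)$kind <- c(rep("protein", np), rep("peptide", nq))
  igraph::V(ig)$members <- c(
    vapply(component$protein_nodes, paste, character(1), collapse = ";"),
    vapply(component$peptide_nodes, paste, character(1), collapse = ";"))
  igraph::V(ig)$is_unique <- c(rep(NA, np), component$is_unique)
  ig
}

#' Export a component as GraphML
#'
#' @param component a \code{bip_component}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_component_graphml <- function(component, path) {
  ig <- component_igraph(component)
  # GraphML has no NA; recode protein-side uniqueness as empty string
  igraph::V(ig)$is_unique <- ifelse(is.na(igraph::V(ig)$is_unique), "",
                                    as.character(igraph::V(ig)$is_unique))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write node and edge lists of a set of components as TSV
#'
#' @param components list of \code{bip_component}.
#' @param node_path,edge_path output TSV paths.
#' @return invisibly, a list with both data frames.
#' @export
write_component_tables <- function(components, node_path, edge_path) {
  nodes <- do.call(rbind, lapply(seq_along(components), function(k) {
    cp <- components[[k]]
    data.frame(
      component = k,
      node = c(paste0("P", seq_along(cp$protein_nodes)),
               paste0("Q", seq_along(cp$peptide_nodes))),
      kind = c(rep("protein", length(cp$protein_nodes)),
               rep("peptide", length(cp$peptide_nodes))),
      is_unique = c(rep(NA, length(cp$protein_nodes)), cp$is_unique),
      members = c(vapply(cp$protein_nodes, paste, character(1),
                         collapse = ";"),
                  vapply(cp$peptide_nodes, paste, character(1),
                         collapse = ";")),
      stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(seq_along(components), function(k) {
    cp <- components[[k]]
    if (nrow(cp$edges) == 0L) return(NULL)
    data.frame(component = k,
               protein = paste0("P", cp$edges[, "protein"]),
               peptide = paste0("Q", cp$edges[, "peptide"]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = nodes, edges = edges))
}
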