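# Fixture databases built from the canonical small motifs. With
# max_missed = 0 these digest to exactly one tryptic peptide per planted
# block (min_len = 5 matches the 5-residue blocks).

fixture_config <- function(max_missed = 0L) {
  digest_config(min_len = 5L, max_len = 50L, max_missed = max_missed)
}

db_M <- function() {
  # A and B each with a unique peptide, one shared peptide
  protein_db_from_headers(c("A", "B"), c("AAAAKVVVVK", "CCCCKVVVVK"))
}

db_N <- function() {
  # B has only the shared peptide
  protein_db_from_headers(c("A", "B"), c("AAAAKVVVVK", "VVVVK"))
}

db_W <- function() {
  # three proteins chained by two shared peptides, no unique peptide
  protein_db_from_headers(c("A", "B", "C"),
                          c("AAAAK", "AAAAKCCCCK", "CCCCK"))
}

db_smallest <- function(acc = "A", block = "DDDDK") {
  protein_db_from_headers(acc, rep(block, length(acc)))
}

components_of <- function(db, config = fixture_config()) {
  components_from_map(digest_database(db, config))
}

m_component <- function() components_of(db_M())[[1L]]
n_component <- function() components_of(db_N())[[1L]]
w_component <- function() components_of(db_W())[[1L]]
smallest_component <- function() components_of(db_smallest())[[1L]]

# build a bip_component directly from node counts and an edge matrix
# (for isomorphism corpora where the graph, not a database, is the point)
comp_from_edges <- function(np, nq, edges,
                            plab = sprintf("P%02d", seq_len(np)),
                            qlab = sprintf("q%02d", seq_len(nq))) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("protein", "peptide")))
  pepgraph:::new_bip_component(as.list(plab), as.list(qlab), edges)
}

# path graph on k alternating nodes; phase = type of the first node
path_component <- function(k, phase = c("protein", "peptide")) {
  phase <- match.arg(phase)
  types <- rep_len(if (phase == "protein") c("P", "q") else c("q", "P"), k)
  np <- sum(types == "P"); nq <- sum(types == "q")
  idx <- integer(k)
  idx[types == "P"] <- seq_len(np)
  idx[types == "q"] <- seq_len(nq)
  e <- cbind(ifelse(types[-k] == "P", idx[-k], idx[-1L]),
             ifelse(types[-k] == "P", idx[-1L], idx[-k]))
  comp_from_edges(np, nq, e)
}

# star: one hub of the given type joined to n leaves of the other type
star_component <- function(n, hub = c("protein", "peptide")) {
  hub <- match.arg(hub)
  if (hub == "protein") comp_from_edges(1L, n, cbind(1L, seq_len(n)))
  else comp_from_edges(n, 1L, cbind(seq_len(n), 1L))
}

# random bipartite graph; every peptide node keeps at least one edge
random_bip_component <- function(np, nq, p_edge = 0.4) {
  m <- matrix(stats::runif(np * nq) < p_edge, np, nq)
  for (j in which(colSums(m) == 0L)) m[sample.int(np, 1L), j] <- TRUE
  for (i in which(rowSums(m) == 0L)) m[i, sample.int(nq, 1L)] <- TRUE
  comp_from_edges(np, nq, which(m, arr.ind = TRUE))
}

# relabel a component: fresh random member names (node order inside the
# component is derived from the names, so this also permutes the nodes)
relabel_component <- function(cp) {
  np <- length(cp$protein_nodes); nq <- length(cp$peptide_nodes)
  plab <- sprintf("X%05d", sample.int(99999L, np))
  qlab <- sprintf("y%05d", sample.int(99999L, nq))
  pepgraph:::new_bip_component(as.list(plab), as.list(qlab), cp$edges)
}

# tiny random synthetic database spec for property sweeps
random_small_spec <- function(seed) {
  synth_spec(n_components = sample(1:5, 1L),
             motif_mix = c(smallest = 0.3, M = 0.25, N = 0.2, W = 0.15,
                           random = 0.1),
             seed = seed)
}
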