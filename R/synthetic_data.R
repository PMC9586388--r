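#' Specification for a synthetic proteome and quant table
#'
#' The generator plants known bipartite graph motifs in an artificial
#' protein database so that every pipeline stage can be checked against
#' analytic ground truth. Motifs (at a 0-missed-cleavage digest):
#' \describe{
#'   \item{smallest}{one protein with two unique blocks: one protein node,
#'     one (collapsed) unique peptide node.}
#'   \item{M}{two proteins, each one unique block plus one shared block:
#'     2 protein / 3 peptide nodes, 1 shared.}
#'   \item{N}{protein A = unique + shared block, protein B = the shared
#'     block only: 2 protein / 2 peptide nodes, B has no unique peptide.}
#'   \item{W}{three proteins chained by two shared blocks: 3 protein /
#'     2 peptide nodes, no unique peptide node at all.}
#'   \item{random}{a random connected bipartite motif (chain of shared
#'     blocks plus density-controlled extras).}
#' }
#' Defaults mirror a spike-in style design: 5 states measured in
#' triplicate, 80\% of theoretical peptides detected, 10\% of replicate
#' values missing, log-normal intensities around 1e7.
#'
#' @param n_components number of planted components (default 100).
#' @param motif_mix named proportions over
#'   \code{c("smallest","M","N","W","random")}; must sum to 1.
#' @param random_motif_params list with \code{max_proteins} and
#'   \code{edge_density} for random motifs.
#' @param isoform_rate probability that an eligible protein (one whose
#'   blocks are all its own, i.e. a smallest-motif protein) gains an
#'   isoform: a copy with one block deleted.
#' @param n_states,n_replicates quant design dimensions.
#' @param detection_prob per-peptide probability of being detected at all.
#' @param missing_prob per-replicate-value probability of missingness.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity model.
#' @param seed integer seed; sub-streams for sequence generation,
#'   detection, intensities and missingness are derived from it so that
#'   changing one parameter does not perturb unrelated draws.
#' @return list of class \code{synth_spec}.
#' @export
synth_spec <- function(n_components = 100L,
                       motif_mix = c(smallest = 0.55, M = 0.20, N = 0.10,
                                     W = 0.05, random = 0.10),
                       random_motif_params = list(max_proteins = 5L,
                                                  edge_density = 0.3),
                       isoform_rate = 0,
                       n_states = 5L, n_replicates = 3L,
                       detection_prob = 0.8, missing_prob = 0.1,
                       intensity_meanlog = log(1e7), intensity_sdlog = 1,
                       seed = 1L) {
  motifs <- c("smallest", "M", "N", "W", "random")
  mix <- stats::setNames(rep(0, 5L), motifs)
  if (is.null(names(motif_mix)) || !all(names(motif_mix) %in% motifs)) {
    stop("motif_mix must be named with a subset of: ",
         paste(motifs, collapse = ", "))
  }
  mix[names(motif_mix)] <- motif_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("motif_mix proportions must sum to 1")
  probs <- c(isoform_rate, detection_prob, missing_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(n_components >= 1L, n_states >= 1L, n_replicates >= 1L)
  structure(list(n_components = as.integer(n_components), motif_mix = mix,
                 random_motif_params = random_motif_params,
                 isoform_rate = isoform_rate,
                 n_states = as.integer(n_states),
                 n_replicates = as.integer(n_replicates),
                 detection_prob = detection_prob,
                 missing_prob = missing_prob,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# exact apportionment of n over proportions: floor + largest remainders
apportion <- function(n, prop) {
  base <- floor(n * prop)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * prop - base
    top <- order(-frac, seq_along(prop))[seq_len(rem)]
    base[top] <- base[top] + 1L
  }
  stats::setNames(as.integer(base), names(prop))
}

# amino acids used inside blocks: no K/R (cut sites) and no P (cut blocker)
.block_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "N", "Q",
                     "S", "T", "V", "W", "Y")

# factory for globally unique tryptic blocks: body from .block_alphabet,
# terminal K/R; an environment-held set guarantees no block is ever reissued
block_factory <- function(min_len, max_len) {
  used <- new.env(parent = emptyenv())
  len_hi <- min(max_len, min_len + 5L)
  function(n) {
    out <- character(0)
    while (length(out) < n) {
      need <- n - length(out)
      lens <- sample(min_len:len_hi, need, replace = TRUE)
      body <- vapply(lens, function(l) {
        paste(sample(.block_alphabet, l - 1L, replace = TRUE), collapse = "")
      }, character(1))
      blocks <- unique(paste0(body, sample(c("K", "R"), need,
                                           replace = TRUE)))
      fresh <- blocks[!vapply(blocks, exists, logical(1), envir = used)]
      for (b in fresh) assign(b, TRUE, envir = used)
      out <- c(out, fresh)
    }
    out[seq_len(n)]
  }
}

#' Generate a synthetic protein database with planted graph motifs
#'
#' Protein sequences are concatenations of globally unique tryptic
#' "blocks" (random residues avoiding K, R and P internally, ending in K
#' or R), so a 0-missed-cleavage digest returns exactly the planted
#' blocks and sharing patterns are controlled by block reuse across
#' proteins. Blocks are unique across components, so planted components
#' can never merge. Isoforms are copies of an eligible parent with one
#' block deleted, accessioned \code{<parent>-2}.
#'
#' @param spec a [synth_spec()].
#' @param config a [digest_config()]; block lengths are drawn within its
#'   length window. The analytic ground truth holds for a digest at
#'   \code{max_missed = 0}.
#' @return list with \code{db} (a \code{protein_db}) and \code{truth}
#'   (list: \code{proteins} data frame accession/component/motif,
#'   \code{blocks} named list accession -> block sequences,
#'   \code{expected_classes} data frame motif/count/protein_nodes/
#'   peptide_nodes, \code{isoforms} character vector).
#' @export
generate_database <- function(spec, config = digest_config(max_missed = 0L)) {
  stopifnot(inherits(spec, "synth_spec"), inherits(config, "digest_config"))
  if (config$min_len + 0L > config$max_len) stop("infeasible length window")
  set.seed(spec$seed)
  counts <- apportion(spec$n_components, spec$motif_mix)
  motif_of <- rep(names(counts), counts)
  make_blocks <- block_factory(config$min_len, config$max_len)

  blocks_needed <- function(m) {
    switch(m, smallest = 2L, M = 3L, N = 2L, W = 2L, random = NA_integer_)
  }
  acc_id <- 0L
  accession <- character(0); sequence <- character(0)
  component <- integer(0); motif <- character(0)
  blocks_of <- list()

  for (k in seq_along(motif_of)) {
    m <- motif_of[k]
    if (m == "random") {
      nprot <- sample(2:max(2L, spec$random_motif_params$max_proteins), 1L)
      chain <- make_blocks(nprot - 1L)
      prot_blocks <- lapply(seq_len(nprot), function(i) {
        c(if (i > 1L) chain[i - 1L], if (i < nprot) chain[i])
      })
      # density-controlled extra shared blocks between non-adjacent pairs
      if (nprot > 2L) {
        for (i in seq_len(nprot - 2L)) for (j in (i + 2L):nprot) {
          if (stats::runif(1) < spec$random_motif_params$edge_density) {
            b <- make_blocks(1L)
            prot_blocks[[i]] <- c(prot_blocks[[i]], b)
            prot_blocks[[j]] <- c(prot_blocks[[j]], b)
          }
        }
      }
      # unique anchor blocks for a random subset of the proteins
      for (i in seq_len(nprot)) {
        if (stats::runif(1) < 0.7) {
          prot_blocks[[i]] <- c(prot_blocks[[i]], make_blocks(1L))
        }
      }
    } else {
      nb <- blocks_needed(m)
      b <- make_blocks(nb)
      prot_blocks <- switch(
        m,
        smallest = list(c(b[1L], b[2L])),
        M = list(c(b[1L], b[3L]), c(b[2L], b[3L])),
        N = list(c(b[1L], b[2L]), b[2L]),
        W = {
          # b1 shared A-B, b2 shared B-C
          list(b[1L], c(b[1L], b[2L]), b[2L])
        })
    }
    for (pb in prot_blocks) {
      acc_id <- acc_id + 1L
      accession <- c(accession, sprintf("SYN%05d", acc_id))
      sequence <- c(sequence, paste(pb, collapse = ""))
      component <- c(component, k)
      motif <- c(motif, m)
      blocks_of[[sprintf("SYN%05d", acc_id)]] <- pb
    }
  }

  # isoforms: only proteins whose blocks are all their own (smallest motif)
  iso_acc <- character(0)
  if (spec$isoform_rate > 0) {
    eligible <- accession[motif == "smallest"]
    gains <- eligible[stats::runif(length(eligible)) < spec$isoform_rate]
    for (parent in gains) {
      child <- paste0(parent, "-2")
      keep <- blocks_of[[parent]][-2L]  # delete the second block
      accession <- c(accession, child)
      sequence <- c(sequence, paste(keep, collapse = ""))
      component <- c(component, component[match(parent, accession)])
      motif <- c(motif, "isoform")
      blocks_of[[child]] <- keep
      iso_acc <- c(iso_acc, child)
    }
  }

  db <- protein_db_from_headers(accession, sequence)
  truth <- list(
    proteins = data.frame(accession = accession, component = component,
                          motif = motif, stringsAsFactors = FALSE),
    blocks = blocks_of,
    expected_classes = expected_motif_classes(counts),
    isoforms = iso_acc)
  list(db = db, truth = truth)
}

# expected database-level classes for the pure motifs (max_missed = 0)
expected_motif_classes <- function(counts) {
  sig <- data.frame(
    motif = c("smallest", "M", "N", "W"),
    protein_nodes = c(1L, 2L, 2L, 3L),
    peptide_nodes = c(1L, 3L, 2L, 2L),
    unique_peptide_nodes = c(1L, 2L, 1L, 0L),
    shared_peptide_nodes = c(0L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
  sig$count <- as.integer(counts[sig$motif])
  sig[sig$count > 0L, , drop = FALSE]
}

#' Generate a synthetic quantitative peptide table
#'
#' Emulates that not all theoretical peptides are quantified: each
#' theoretical peptide of the database digest is detected with
#' \code{detection_prob}; detected peptides get i.i.d. log-normal
#' intensities per sample, and each replicate value is then independently
#' set missing with \code{missing_prob}. Zeros are never emitted.
#' Detection, intensity and missingness draws use separate seed streams.
#'
#' @param db a \code{protein_db}, typically from [generate_database()].
#' @param spec the [synth_spec()].
#' @param config digest used to enumerate theoretical peptides (default
#'   0 missed cleavages, the generator's analytic mode).
#' @param force_detect,force_miss optional character vectors of peptide
#'   sequences whose detection is forced on/off regardless of the draws
#'   (for constructing targeted degradation masks).
#' @return a \code{quant_table}; the detection mask is attached as
#'   \code{attr(, "detected")}.
#' @export
generate_quant_table <- function(db, spec,
                                 config = digest_config(max_missed = 0L),
                                 force_detect = character(0),
                                 force_miss = character(0)) {
  stopifnot(inherits(db, "protein_db"), inherits(spec, "synth_spec"))
  map <- digest_database(db, config)
  peptides <- names(map$entries)
  design <- data.frame(
    sample = paste0("S", rep(seq_len(spec$n_states),
                             each = spec$n_replicates),
                    "_R", rep(seq_len(spec$n_replicates), spec$n_states)),
    state = paste0("S", rep(seq_len(spec$n_states),
                            each = spec$n_replicates)),
    replicate = rep(seq_len(spec$n_replicates), spec$n_states),
    stringsAsFactors = FALSE)

  set.seed(spec$seed + 1L)  # detection stream
  detected <- stats::runif(length(peptides)) < spec$detection_prob
  names(detected) <- peptides
  detected[peptides %in% force_detect] <- TRUE
  detected[peptides %in% force_miss] <- FALSE

  det <- peptides[detected]
  n <- length(det); s <- nrow(design)
  set.seed(spec$seed + 2L)  # intensity stream
  intensity <- matrix(stats::rlnorm(n * s, spec$intensity_meanlog,
                                    spec$intensity_sdlog),
                      nrow = n, ncol = s,
                      dimnames = list(NULL, design$sample))
  set.seed(spec$seed + 3L)  # missingness stream
  if (spec$missing_prob > 0 && n > 0L) {
    intensity[matrix(stats::runif(n * s) < spec$missing_prob, n, s)] <-
      NA_real_
  }
  tb <- quant_table(det, intensity, design)
  attr(tb, "detected") <- detected
  tb
}

#' Two opposing effects of moving from database to quantitative level
#'
#' Larger graphs split up when shared peptides go unquantified (raising
#' the proportion of single-protein-node graphs), while protein nodes
#' lose their unique peptides when those go unquantified (raising the
#' proportion of protein nodes with only shared peptides). Reports both
#' proportions at each level and their deltas (quant minus database).
#'
#' @param db_components components at database level.
#' @param quant_components components at quantitative level (pooled, if
#'   several comparisons).
#' @return named list with per-level proportions and the two deltas.
#' @export
degradation_report <- function(db_components, quant_components) {
  prop_single <- function(comps) {
    if (length(comps) == 0L) return(NA_real_)
    mean(vapply(comps, function(cp) length(cp$protein_nodes), 1L) == 1L)
  }
  prop_only_shared <- function(comps) {
    if (length(comps) == 0L) return(NA_real_)
    uniqueness_breakdown(comps)$protein_nodes_only_shared_pct / 100
  }
  db_s <- prop_single(db_components); qt_s <- prop_single(quant_components)
  db_o <- prop_only_shared(db_components)
  qt_o <- prop_only_shared(quant_components)
  list(single_protein_graphs_db = db_s,
       single_protein_graphs_quant = qt_s,
       delta_single_protein_graphs = qt_s - db_s,
       only_shared_protein_nodes_db = db_o,
       only_shared_protein_nodes_quant = qt_o,
       delta_only_shared_protein_nodes = qt_o - db_o)
}

#' Write a synthetic data set to disk
#'
#' FASTA database, quant CSV (wide, one column per sample) and a
#' ground-truth JSON.
#'
#' @param gen output of [generate_database()].
#' @param table a \code{quant_table} from [generate_quant_table()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths.
#' @export
write_synthetic_dataset <- function(gen, table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "synthetic_db.fasta")
  quant <- file.path(dir, "synthetic_quant.csv")
  truth <- file.path(dir, "synthetic_truth.json")
  write_fasta(gen$db, fasta)
  df <- data.frame(Sequence = table$peptide, table$intensity,
                   check.names = FALSE)
  utils::write.csv(df, quant, row.names = FALSE)
  jsonlite::write_json(
    list(proteins = gen$truth$proteins,
         expected_classes = gen$truth$expected_classes,
         isoforms = gen$truth$isoforms,
         design = table$design),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, quant = quant, truth = truth))
}
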