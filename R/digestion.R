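#' Digestion settings for in silico trypsin digestion
#'
#' Trypsin cuts C-terminally of K and R unless the next residue is P
#' (the classical "no cutting before proline" rule). Peptides outside the
#' length window or with more than \code{max_missed} internal cleavage
#' sites are discarded. Length bounds are inclusive on both ends.
#'
#' @param min_len minimum peptide length in amino acids (default 7, a
#'   common search-engine default; 5, 6 and 9 are typical alternatives).
#' @param max_len maximum peptide length in amino acids (default 50).
#' @param max_missed maximum number of missed cleavage sites (default 2).
#' @param enzyme cleavage rule identifier; only \code{"trypsin-no-P"} is
#'   defined.
#' @return A list of class \code{digest_config}.
#' @export
digest_config <- function(min_len = 7L, max_len = 50L, max_missed = 2L,
                          enzyme = "trypsin-no-P") {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  max_missed <- as.integer(max_missed)
  if (min_len < 1L || min_len > max_len) {
    stop("digest_config: need 1 <= min_len <= max_len")
  }
  if (max_missed < 0L) stop("digest_config: max_missed must be >= 0")
  if (!identical(enzyme, "trypsin-no-P")) {
    stop("digest_config: unknown enzyme '", enzyme, "'")
  }
  structure(list(min_len = min_len, max_len = max_len,
                 max_missed = max_missed, enzyme = enzyme),
            class = "digest_config")
}

#' Tryptic cleavage sites of a sequence
#'
#' Positions \code{i} (1-based, the cut falls after residue \code{i}) such
#' that residue \code{i} is K or R, \code{i} is not the last residue, and
#' residue \code{i + 1} is not P.
#'
#' @param sequence non-empty uppercase amino-acid string.
#' @return integer vector of cut positions in ascending order.
#' @export
cleavage_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  idx <- seq_len(n - 1L)
  idx[res[idx] %in% c("K", "R") & res[idx + 1L] != "P"]
}

#' Digest one protein sequence in silico
#'
#' Fully cleaved fragments are the substrings between consecutive cut
#' positions (plus sequence start and end); a peptide with \code{k} missed
#' cleavages is the concatenation of \code{k + 1} consecutive fragments.
#' All concatenations with \code{k <= max_missed} whose length falls in
#' \code{[min_len, max_len]} are returned. Identical sequences arising at
#' different positions of the same protein are emitted once, keeping the
#' smallest missed-cleavage count.
#'
#' @param sequence non-empty uppercase amino-acid string.
#' @param config a [digest_config()].
#' @return data frame with columns \code{sequence} and
#'   \code{missed_cleavages}; zero rows if nothing survives the filters.
#' @export
digest <- function(sequence, config = digest_config()) {
  stopifnot(inherits(config, "digest_config"))
  cuts <- cleavage_sites(sequence)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(sequence))
  nfrag <- length(starts)
  peps <- character(0); mcs <- integer(0)
  for (k in 0:min(config$max_missed, nfrag - 1L)) {
    i <- seq_len(nfrag - k)
    len <- ends[i + k] - starts[i] + 1L
    keep <- len >= config$min_len & len <= config$max_len
    if (any(keep)) {
      peps <- c(peps, substring(sequence, starts[i][keep], ends[i + k][keep]))
      mcs <- c(mcs, rep.int(k, sum(keep)))
    }
  }
  # smallest k wins: rows are already in ascending k order
  first <- !duplicated(peps)
  data.frame(sequence = peps[first], missed_cleavages = mcs[first],
             stringsAsFactors = FALSE)
}

#' Digest a whole protein database into a peptide-protein map
#'
#' Runs [digest()] on every record and inverts the result into the
#' uncollapsed biadjacency: a mapping from each surviving peptide sequence
#' to the set of accessions containing it as a tryptic peptide. Accessions
#' with no surviving peptide are listed as excluded.
#'
#' @param db a \code{protein_db} data frame (see [read_fasta()]).
#' @param config a [digest_config()].
#' @param include_decoys if \code{FALSE} (default) decoy records are
#'   dropped before digestion.
#' @return An object of class \code{pep_map}: list with \code{entries}
#'   (named list, peptide sequence -> sorted character vector of
#'   accessions), \code{included_accessions}, \code{excluded_accessions},
#'   and the \code{config} used.
#' @export
digest_database <- function(db, config = digest_config(),
                            include_decoys = FALSE) {
  stopifnot(inherits(db, "protein_db"), inherits(config, "digest_config"))
  if (!include_decoys) db <- db[!db$is_decoy, , drop = FALSE]
  acc_rep <- character(0); pep_all <- character(0)
  excluded <- character(0)
  for (i in seq_len(nrow(db))) {
    dg <- digest(db$sequence[i], config)
    if (nrow(dg) == 0L) {
      excluded <- c(excluded, db$accession[i])
    } else {
      pep_all <- c(pep_all, dg$sequence)
      acc_rep <- c(acc_rep, rep.int(db$accession[i], nrow(dg)))
    }
  }
  entries <- if (length(pep_all)) {
    lapply(split(acc_rep, pep_all), function(a) sort(unique(a)))
  } else {
    structure(list(), names = character(0))
  }
  pep_map(entries,
          included_accessions = setdiff(db$accession, excluded),
          excluded_accessions = excluded,
          config = config)
}

#' Construct a peptide-protein map
#'
#' @param entries named list mapping peptide sequence to a non-empty
#'   character vector of accessions.
#' @param included_accessions accessions with at least one mapped peptide.
#' @param excluded_accessions accessions with none.
#' @param config optional [digest_config()] that produced the map
#'   (\code{NULL} for maps of measured peptides).
#' @return An object of class \code{pep_map}.
#' @export
pep_map <- function(entries, included_accessions,
                    excluded_accessions = character(0), config = NULL) {
  stopifnot(is.list(entries))
  if (length(entries)) {
    stopifnot(!is.null(names(entries)), all(nzchar(names(entries))),
              !anyDuplicated(names(entries)),
              all(lengths(entries) > 0L))
  }
  structure(list(entries = entries,
                 included_accessions = sort(unique(included_accessions)),
                 excluded_accessions = sort(unique(excluded_accessions)),
                 config = config),
            class = "pep_map")
}

#' @export
print.pep_map <- function(x, ...) {
  cat("pep_map:", length(x$entries), "peptides over",
      length(x$included_accessions), "accessions (",
      length(x$excluded_accessions), "excluded )\n")
  invisible(x)
}

#' Export a peptide-protein map as a delimited table
#'
#' One row per peptide: sequence and semicolon-joined accessions.
#'
#' @param map a \code{pep_map}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_pep_map <- function(map, path) {
  stopifnot(inherits(map, "pep_map"))
  df <- data.frame(
    peptide = names(map$entries),
    accessions = vapply(map$entries, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
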