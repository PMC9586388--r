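#' Read a protein sequence database from FASTA
#'
#' Parses a (possibly multi-line) FASTA file into a protein database
#' data frame. UniProt-style headers of the form \code{db|ACC|NAME desc}
#' yield \code{accession = ACC} and \code{entry_name = NAME}; any other
#' header yields the first whitespace-delimited token as accession.
#' Sequences are uppercased and a single trailing \code{*} is stripped.
#'
#' Non-standard residues (B, J, O, U, X, Z) are accepted as ordinary
#' characters: no masses are computed downstream, only sequence identity,
#' so they take part in digestion and substring matching literally. I and
#' L are never merged.
#'
#' @param path path to a FASTA file.
#' @param decoy_prefix entries whose first header token starts with this
#'   prefix are flagged as decoys (default \code{"DECOY_"}).
#' @return A data frame of class \code{protein_db} with columns
#'   \code{accession}, \code{entry_name}, \code{description},
#'   \code{sequence}, \code{is_decoy}, \code{base_accession}.
#' @export
read_fasta <- function(path, decoy_prefix = "DECOY_") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("FASTA file contains no entries: ", path)
  protein_db_from_headers(names(aas), as.character(aas), decoy_prefix)
}

#' Build a protein database from raw headers and sequences
#'
#' Lower-level constructor behind [read_fasta()]; useful when records come
#' from a generator rather than a file.
#'
#' @param headers FASTA header lines without the leading \code{>}.
#' @param sequences amino-acid strings, parallel to \code{headers}.
#' @inheritParams read_fasta
#' @return A \code{protein_db} data frame; see [read_fasta()].
#' @export
protein_db_from_headers <- function(headers, sequences,
                                    decoy_prefix = "DECOY_") {
  stopifnot(length(headers) == length(sequences))
  headers <- unname(as.character(headers))
  sequences <- unname(as.character(sequences))
  first_tok <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  parts <- strsplit(first_tok, "|", fixed = TRUE)
  npart <- lengths(parts)
  accession <- as.character(ifelse(
    npart >= 3L, vapply(parts, function(p) p[2L], character(1)), first_tok))
  entry_name <- as.character(ifelse(
    npart >= 3L, vapply(parts, function(p) p[3L], character(1)), ""))
  is_decoy <- startsWith(first_tok, decoy_prefix)

  seqs <- toupper(sequences)
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("FASTA entry with empty sequence: ",
         paste(accession[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    offending <- unique(unlist(strsplit(gsub("[A-Z]", "", seqs[bad]), "")))
    stop("Sequence characters outside A-Z for ",
         paste(accession[bad], collapse = ", "),
         " (offending: ", paste(offending, collapse = " "), ")")
  }
  dup <- duplicated(accession)
  if (any(dup)) {
    stop("Duplicate accession(s) in database: ",
         paste(unique(accession[dup]), collapse = ", "))
  }

  db <- data.frame(
    accession = accession,
    entry_name = entry_name,
    description = desc,
    sequence = seqs,
    is_decoy = is_decoy,
    base_accession = if (length(accession)) base_accession(accession)
                     else character(0),
    stringsAsFactors = FALSE
  )
  rownames(db) <- NULL
  class(db) <- c("protein_db", "data.frame")
  db
}

#' Write a protein database back to FASTA
#'
#' Headers are reconstructed so that re-reading with [read_fasta()] (and the
#' same decoy prefix) reproduces the records: UniProt-style for entries with
#' an \code{entry_name}, bare accession otherwise.
#'
#' @param db a \code{protein_db} data frame.
#' @param path output file path.
#' @param decoy_prefix prefix prepended to the header of pipe-style decoy
#'   entries (plain-accession decoys already carry it in the accession).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(db, path, decoy_prefix = "DECOY_") {
  stopifnot(inherits(db, "protein_db"))
  tag <- ifelse(db$is_decoy & nzchar(db$entry_name),
                paste0(decoy_prefix, "sp"), "sp")
  head <- ifelse(nzchar(db$entry_name),
                 paste0(tag, "|", db$accession, "|", db$entry_name),
                 db$accession)
  head <- ifelse(nzchar(db$description),
                 paste(head, db$description), head)
  aas <- Biostrings::AAStringSet(db$sequence)
  names(aas) <- head
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Strip a UniProt isoform suffix from an accession
#'
#' \code{"P12345-2"} becomes \code{"P12345"}; accessions without a trailing
#' \code{-<digits>} suffix are returned unchanged. Used to group isoforms
#' under their parent accession when classifying isoform-unique peptides.
#'
#' @param accession character vector of accessions.
#' @return character vector of base accessions.
#' @export
base_accession <- function(accession) {
  stopifnot(is.character(accession), all(nzchar(accession)))
  sub("-[0-9]+$", "", accession)
}
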