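#' Quantitative peptide table
#'
#' Container for a peptide-level intensity table together with the sample
#' design (which sample belongs to which state/replicate). Intensities are
#' positive reals or \code{NA}; zeros are converted to \code{NA} by
#' [filter_quant_peptides()] before any aggregation.
#'
#' @param peptide character vector of peptide sequences (one per row).
#' @param intensity numeric matrix, rows parallel to \code{peptide},
#'   columns named by sample.
#' @param design data frame with columns \code{sample}, \code{state},
#'   \code{replicate}; every intensity column must appear in
#'   \code{design$sample}.
#' @param modification optional character vector of modification
#'   descriptors (rows then keyed by peptide x modification; collapse with
#'   [aggregate_ptm_rows()]).
#' @param decoy_only logical vector: row stems exclusively from decoy
#'   proteins.
#' @return An object of class \code{quant_table}.
#' @export
quant_table <- function(peptide, intensity, design, modification = NULL,
                        decoy_only = FALSE) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  stopifnot(is.character(peptide), nrow(intensity) == length(peptide),
            !is.null(colnames(intensity)),
            all(c("sample", "state", "replicate") %in% names(design)))
  if (!all(colnames(intensity) %in% design$sample)) {
    stop("intensity columns missing from design: ",
         paste(setdiff(colnames(intensity), design$sample), collapse = ", "))
  }
  decoy_only <- rep_len(as.logical(decoy_only), length(peptide))
  if (!is.null(modification)) {
    modification <- rep_len(as.character(modification), length(peptide))
  }
  if (any(intensity < 0, na.rm = TRUE)) stop("negative intensities")
  structure(list(peptide = peptide, modification = modification,
                 intensity = intensity,
                 design = as.data.frame(design), decoy_only = decoy_only),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table:", length(x$peptide), "rows x",
      ncol(x$intensity), "samples;",
      length(unique(x$design$state)), "states\n")
  invisible(x)
}

#' Read a quantitative peptide table from delimited text
#'
#' Generic wide-format reader: one column holds the peptide sequence,
#' a set of columns holds per-sample intensities. A column-mapping config
#' names them explicitly so arbitrary dialects can be read.
#'
#' @param path delimited text file.
#' @param design sample design data frame (\code{sample}, \code{state},
#'   \code{replicate}).
#' @param sequence_col name of the peptide sequence column.
#' @param intensity_cols named character vector mapping sample name ->
#'   column name; if \code{NULL}, columns named exactly as
#'   \code{design$sample} are used.
#' @param modification_col optional modification descriptor column.
#' @param decoy_col optional column; rows where it equals
#'   \code{decoy_flag} are marked decoy-only.
#' @param decoy_flag value of \code{decoy_col} marking decoy-only rows
#'   (default \code{"+"}, the MaxQuant convention).
#' @param sep field separator (default tab).
#' @return A \code{quant_table}.
#' @export
read_quant_table <- function(path, design, sequence_col = "Sequence",
                             intensity_cols = NULL,
                             modification_col = NULL,
                             decoy_col = NULL, decoy_flag = "+",
                             sep = "\t") {
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(intensity_cols)) {
    intensity_cols <- stats::setNames(design$sample, design$sample)
  }
  missing_cols <- setdiff(c(sequence_col, unname(intensity_cols)), names(df))
  if (length(missing_cols)) {
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  intensity <- as.matrix(df[, unname(intensity_cols), drop = FALSE])
  colnames(intensity) <- names(intensity_cols)
  decoy_only <- if (!is.null(decoy_col) && decoy_col %in% names(df)) {
    !is.na(df[[decoy_col]]) & df[[decoy_col]] == decoy_flag
  } else FALSE
  modification <- if (!is.null(modification_col)) df[[modification_col]]
  quant_table(df[[sequence_col]], intensity, design,
              modification = modification, decoy_only = decoy_only)
}

#' Read a MaxQuant-style peptides.txt table
#'
#' Convenience preset over [read_quant_table()]: sequence from
#' \code{Sequence}, intensities from \code{Intensity <sample>} columns,
#' decoy-only rows from \code{Reverse == "+"}.
#'
#' @inheritParams read_quant_table
#' @param intensity_prefix prefix of the per-sample intensity columns.
#' @export
read_maxquant_peptides <- function(path, design,
                                   intensity_prefix = "Intensity ",
                                   sep = "\t") {
  cols <- stats::setNames(paste0(intensity_prefix, design$sample),
                          design$sample)
  read_quant_table(path, design, sequence_col = "Sequence",
                   intensity_cols = cols, decoy_col = "Reverse",
                   decoy_flag = "+", sep = sep)
}

#' Sum intensities over modification variants of the same sequence
#'
#' Per (sequence, sample), intensities of all modification variants are
#' summed; missing values count as 0 in the sum unless every variant is
#' missing, in which case the result stays missing.
#'
#' @param table a \code{quant_table} whose rows are keyed by
#'   (peptide, modification).
#' @return A \code{quant_table} with one row per distinct sequence and
#'   \code{modification = NULL}.
#' @export
aggregate_ptm_rows <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  seqs <- unique(table$peptide)
  idx <- split(seq_along(table$peptide), factor(table$peptide, levels = seqs))
  agg <- t(vapply(idx, function(i) {
    m <- table$intensity[i, , drop = FALSE]
    s <- colSums(m, na.rm = TRUE)
    s[colSums(!is.na(m)) == 0L] <- NA_real_
    s
  }, numeric(ncol(table$intensity))))
  colnames(agg) <- colnames(table$intensity)
  decoy <- vapply(idx, function(i) all(table$decoy_only[i]), logical(1))
  quant_table(seqs, agg, table$design, decoy_only = decoy)
}

#' Filter a quant table to analyzable peptides
#'
#' Drops decoy-only rows, drops rows whose sequence length falls outside
#' the digestion length window (so measured peptides stay directly
#' comparable with the theoretical ones), and replaces zero intensities by
#' missing values.
#'
#' @param table a \code{quant_table}.
#' @param config a [digest_config()] supplying the length window.
#' @return The filtered \code{quant_table}.
#' @export
filter_quant_peptides <- function(table, config = digest_config()) {
  stopifnot(inherits(table, "quant_table"), inherits(config, "digest_config"))
  len <- nchar(table$peptide)
  keep <- !table$decoy_only & len >= config$min_len & len <= config$max_len
  intensity <- table$intensity[keep, , drop = FALSE]
  intensity[intensity == 0] <- NA_real_
  quant_table(table$peptide[keep], intensity, table$design,
              modification = if (!is.null(table$modification))
                table$modification[keep],
              decoy_only = FALSE)
}

#' Map measured peptide sequences onto database proteins
#'
#' Each peptide maps to every non-decoy protein whose sequence contains it
#' as a substring (mirroring how search engines assign peptides; the
#' tryptic constraint acts upstream at identification). Peptides matching
#' no protein are reported via a message and excluded from the map.
#'
#' @param sequences character vector of peptide sequences.
#' @param db a \code{protein_db}.
#' @return A \code{pep_map} (with \code{config = NULL}); unmapped
#'   sequences are stored in its \code{unmapped_peptides} element.
#' @export
map_quant_peptides <- function(sequences, db) {
  stopifnot(is.character(sequences), inherits(db, "protein_db"))
  db <- db[!db$is_decoy, , drop = FALSE]
  sequences <- unique(sequences)
  hits <- lapply(sequences, function(p) {
    db$accession[grepl(p, db$sequence, fixed = TRUE)]
  })
  names(hits) <- sequences
  unmapped <- sequences[lengths(hits) == 0L]
  if (length(unmapped)) {
    message(length(unmapped), " peptide(s) mapped to no database protein",
            " and were excluded")
  }
  hits <- lapply(hits[lengths(hits) > 0L], sort)
  mapped_acc <- unique(unlist(hits, use.names = FALSE))
  m <- pep_map(hits,
               included_accessions = mapped_acc,
               excluded_accessions = setdiff(db$accession, mapped_acc))
  m$unmapped_peptides <- unmapped
  m
}

#' Combine replicate intensities of one peptide in one state
#'
#' Arithmetic mean of the non-missing values when at least
#' \code{min_valid} of them are present, otherwise missing. With the
#' default \code{min_valid = 2} and triplicates this is the rule "if two
#' or more of the three values are missing, the combined intensity is
#' missing".
#'
#' @param values numeric vector of replicate intensities (NA = missing).
#' @param min_valid minimum number of non-missing values required.
#' @return scalar mean or \code{NA}.
#' @export
aggregate_replicates <- function(values, min_valid = 2L) {
  if (min_valid < 1L) stop("min_valid must be >= 1")
  ok <- !is.na(values)
  if (sum(ok) >= min_valid) mean(values[ok]) else NA_real_
}

#' Peptide ratios between two states
#'
#' Replicates of each state are combined with [aggregate_replicates()];
#' the per-peptide ratio is mean(A) / mean(B), missing whenever either
#' aggregated mean is missing. Ratios are of raw (not log) intensities and
#' of means, not means of ratios.
#'
#' @param table a preprocessed \code{quant_table}.
#' @param state_a,state_b state labels from the design; \code{state_a} is
#'   the numerator.
#' @param min_valid passed to [aggregate_replicates()].
#' @return An object of class \code{comparison_ratios}: list with
#'   \code{comparison = c(state_a, state_b)}, named numeric \code{ratios}
#'   (NA = invalid) and \code{valid_peptides}.
#' @export
compute_ratios <- function(table, state_a, state_b, min_valid = 2L) {
  stopifnot(inherits(table, "quant_table"))
  states <- unique(table$design$state)
  if (!state_a %in% states || !state_b %in% states) {
    stop("unknown state label: ",
         paste(setdiff(c(state_a, state_b), states), collapse = ", "))
  }
  state_mean <- function(st) {
    cols <- table$design$sample[table$design$state == st]
    m <- table$intensity[, cols, drop = FALSE]
    apply(m, 1L, aggregate_replicates, min_valid = min_valid)
  }
  ratios <- state_mean(state_a) / state_mean(state_b)
  names(ratios) <- table$peptide
  structure(list(comparison = c(state_a, state_b),
                 ratios = ratios,
                 valid_peptides = table$peptide[!is.na(ratios)]),
            class = "comparison_ratios")
}

#' Enumerate pairwise state comparisons
#'
#' All unordered pairs of the given states, each ordered by the states'
#' sort order (numerator = earlier state); the enumeration itself follows
#' the same order.
#'
#' @param states character vector of state labels (need not be unique).
#' @return data frame with columns \code{state_a}, \code{state_b}.
#' @export
state_comparisons <- function(states) {
  s <- sort(unique(states))
  if (length(s) < 2L) {
    return(data.frame(state_a = character(0), state_b = character(0)))
  }
  pairs <- utils::combn(s, 2L)
  data.frame(state_a = pairs[1L, ], state_b = pairs[2L, ],
             stringsAsFactors = FALSE)
}
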