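design3 <- function(n_states = 2L, n_rep = 3L) {
  data.frame(sample = paste0("S", rep(1:n_states, each = n_rep),
                             "_R", rep(1:n_rep, n_states)),
             state = paste0("S", rep(1:n_states, each = n_rep)),
             replicate = rep(1:n_rep, n_states))
}

test_that("PTM variant rows are summed, all-missing stays missing", {
  d <- design3(1L, 2L)
  tb <- quant_table(c("PEPK", "PEPK", "AAAK"),
                    matrix(c(10, 5, 7,
                             NA, 2, NA), ncol = 2,
                           dimnames = list(NULL, d$sample)),
                    d, modification = c("mod1", "mod2", ""))
  agg <- aggregate_ptm_rows(tb)
  expect_equal(agg$peptide, c("PEPK", "AAAK"))
  expect_equal(unname(agg$intensity[1, ]), c(15, 2))  # NA counts as 0
  expect_equal(unname(agg$intensity[2, ]), c(7, NA))  # all variants missing
})

test_that("filtering drops decoy-only and out-of-length rows, zeros to NA", {
  d <- design3(1L, 2L)
  tb <- quant_table(c("AAAAAAAK", "CCCCCCCK", "SHRT", "DDDDDDDK"),
                    matrix(c(1, 2, 3, 0,
                             5, 6, 7, 8), ncol = 2,
                           dimnames = list(NULL, d$sample)),
                    d, decoy_only = c(FALSE, TRUE, FALSE, FALSE))
  out <- filter_quant_peptides(tb, digest_config(min_len = 7L))
  expect_equal(out$peptide, c("AAAAAAAK", "DDDDDDDK"))
  expect_equal(unname(out$intensity[2, ]), c(NA, 8))
})

test_that("quant peptides map to all containing proteins by substring", {
  db <- protein_db_from_headers(c("A", "B", "DECOY_D"),
                                c("AAAAKVVVVK", "CCCCKVVVVK", "VVVVK"))
  expect_message(m <- map_quant_peptides(c("VVVVK", "WWWWW", "CCCCKVVVVK"),
                                         db),
                 "1 peptide")
  expect_equal(m$entries$VVVVK, c("A", "B"))   # decoys never match
  expect_equal(m$entries$CCCCKVVVVK, "B")      # equality counts as substring
  expect_equal(m$unmapped_peptides, "WWWWW")
})

test_that("mapping of a theoretical tryptic peptide agrees with the digest", {
  sp <- random_small_spec(11L)
  cfg <- fixture_config()
  gen <- generate_database(sp, cfg)
  dig <- digest_database(gen$db, cfg)
  some <- names(dig$entries)[seq(1L, length(dig$entries), by = 2L)]
  qm <- suppressMessages(map_quant_peptides(some, gen$db))
  for (p in some) expect_equal(qm$entries[[p]], dig$entries[[p]])
})

test_that("replicate aggregation needs min_valid non-missing values", {
  expect_equal(aggregate_replicates(c(10, 20, NA)), 15)
  expect_true(is.na(aggregate_replicates(c(10, NA, NA))))
  expect_equal(aggregate_replicates(c(10, 10, 10)), 10)
  expect_equal(aggregate_replicates(c(10, NA, NA), min_valid = 1L), 10)
  expect_error(aggregate_replicates(c(1, 2), min_valid = 0L), "min_valid")
})

test_that("ratios are means ratios, missing propagates, swap inverts", {
  d <- design3()
  set.seed(1)
  x <- matrix(rlnorm(5 * 6, 10, 1), nrow = 5,
              dimnames = list(NULL, d$sample))
  x[1, 1:2] <- NA            # S1 mean missing -> ratio missing
  x[2, 4] <- NA              # still 2 valid in S2
  tb <- quant_table(paste0("PEP", 1:5, "K"), x, d)
  cr <- compute_ratios(tb, "S1", "S2")
  expect_true(is.na(cr$ratios[["PEP1K"]]))
  expect_equal(cr$ratios[["PEP2K"]],
               mean(x[2, 1:3]) / mean(x[2, 5:6]))
  expect_setequal(cr$valid_peptides, paste0("PEP", 2:5, "K"))
  # swapping states inverts every valid ratio and keeps the valid set
  rev <- compute_ratios(tb, "S2", "S1")
  expect_setequal(rev$valid_peptides, cr$valid_peptides)
  expect_equal(rev$ratios[cr$valid_peptides],
               1 / cr$ratios[cr$valid_peptides])
  # permuting replicates within a state changes nothing
  perm <- c(3, 1, 2, 4, 5, 6)
  tb2 <- quant_table(tb$peptide, x[, perm],
                     d[match(colnames(x)[perm], d$sample), ])
  expect_equal(compute_ratios(tb2, "S1", "S2")$ratios, cr$ratios)
  expect_error(compute_ratios(tb, "S1", "S9"), "unknown state")
})

test_that("valid peptides have enough replicates in both states", {
  d <- design3()
  set.seed(2)
  x <- matrix(rlnorm(30 * 6, 10, 1), nrow = 30,
              dimnames = list(NULL, d$sample))
  x[runif(length(x)) < 0.4] <- NA
  tb <- quant_table(sprintf("P%02dK", 1:30), x, d)
  cr <- compute_ratios(tb, "S1", "S2", min_valid = 2L)
  enough <- rowSums(!is.na(x[, 1:3])) >= 2 & rowSums(!is.na(x[, 4:6])) >= 2
  expect_setequal(cr$valid_peptides, tb$peptide[enough])
})

test_that("comparisons enumerate unordered pairs in state sort order", {
  cmp <- state_comparisons(c("S2", "S1", "S3", "S1"))
  expect_equal(cmp$state_a, c("S1", "S1", "S2"))
  expect_equal(cmp$state_b, c("S2", "S3", "S3"))
  expect_equal(nrow(state_comparisons(paste0("S", 1:5))), 10L)
  expect_equal(nrow(state_comparisons("S1")), 0L)
})

test_that("delimited readers reproduce a written table", {
  d <- design3(2L, 2L)
  f <- withr::local_tempfile(fileext = ".txt")
  df <- data.frame(Sequence = c("AAAAAAAK", "CCCCCCCK"),
                   `Intensity S1_R1` = c(1, 2),
                   `Intensity S1_R2` = c(3, 4),
                   `Intensity S2_R1` = c(5, 6),
                   `Intensity S2_R2` = c(7, 8),
                   Reverse = c("", "+"), check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- read_maxquant_peptides(f, d)
  expect_equal(tb$peptide, df$Sequence)
  expect_equal(tb$decoy_only, c(FALSE, TRUE))
  expect_equal(unname(tb$intensity[, "S2_R1"]), c(5, 6))
})
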