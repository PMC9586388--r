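test_that("spec validation rejects bad mixes and probabilities", {
  expect_error(synth_spec(motif_mix = c(M = 0.5)), "sum to 1")
  expect_error(synth_spec(motif_mix = c(Z = 1)), "named")
  expect_error(synth_spec(detection_prob = 1.2), "\\[0, 1\\]")
})

test_that("pure-motif databases recover exactly their planted class", {
  cfg <- digest_config(min_len = 7L, max_missed = 0L)
  cases <- list(
    list(motif = "smallest", n = 50L, sig = c(1L, 1L)),
    list(motif = "M", n = 20L, sig = c(2L, 3L)),
    list(motif = "N", n = 20L, sig = c(2L, 2L)),
    list(motif = "W", n = 20L, sig = c(3L, 2L)))
  for (cs in cases) {
    mix <- stats::setNames(1, cs$motif)
    gen <- generate_database(synth_spec(n_components = cs$n,
                                        motif_mix = mix, seed = 17L), cfg)
    res <- run_fasta_level(gen$db, cfg, verbose = FALSE)
    expect_equal(nrow(res$classes), 1L, info = cs$motif)
    expect_equal(res$classes$count, cs$n, info = cs$motif)
    expect_equal(c(res$classes$protein_nodes, res$classes$peptide_nodes),
                 cs$sig, info = cs$motif)
    truthc <- gen$truth$expected_classes
    expect_equal(truthc$count, cs$n)
    expect_equal(c(truthc$protein_nodes, truthc$peptide_nodes), cs$sig)
  }
})

test_that("same seed gives byte-identical FASTA, streams are split", {
  sp <- synth_spec(n_components = 10L, seed = 23L)
  cfg <- fixture_config()
  d1 <- withr::local_tempfile(fileext = ".fasta")
  d2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(generate_database(sp, cfg)$db, d1)
  write_fasta(generate_database(sp, cfg)$db, d2)
  expect_identical(readLines(d1), readLines(d2))

  # changing the missingness parameter must not perturb detection draws
  gen <- generate_database(sp, cfg)
  t1 <- generate_quant_table(gen$db, sp, cfg)
  sp2 <- sp; sp2$missing_prob <- 0
  t2 <- generate_quant_table(gen$db, sp2, cfg)
  expect_identical(attr(t1, "detected"), attr(t2, "detected"))
})

test_that("full detection reproduces the database graphs, zero kills all", {
  cfg <- fixture_config()
  sp <- synth_spec(n_components = 15L,
                   motif_mix = c(smallest = 0.4, M = 0.3, N = 0.2, W = 0.1),
                   n_states = 2L, detection_prob = 1, missing_prob = 0,
                   seed = 31L)
  gen <- generate_database(sp, cfg)
  db_res <- run_fasta_level(gen$db, cfg, verbose = FALSE)
  tb <- generate_quant_table(gen$db, sp, cfg)
  q_res <- run_quant_level(gen$db, tb, cfg, verbose = FALSE)
  expect_equal(q_res$summary$graphs, db_res$summary$graphs)
  expect_equal(q_res$classes[, c("key", "count")],
               db_res$classes[, c("key", "count")])

  sp0 <- sp; sp0$detection_prob <- 0
  expect_length(generate_quant_table(gen$db, sp0, cfg)$peptide, 0L)
})

test_that("losing the shared peptide splits an M into two smallest", {
  cfg <- fixture_config()
  sp <- synth_spec(n_components = 8L, motif_mix = c(M = 1),
                   n_states = 2L, detection_prob = 1, missing_prob = 0,
                   seed = 41L)
  gen <- generate_database(sp, cfg)
  prot <- gen$truth$proteins
  shared <- vapply(unique(prot$component), function(k) {
    accs <- prot$accession[prot$component == k]
    intersect(gen$truth$blocks[[accs[1L]]],
              gen$truth$blocks[[accs[2L]]])
  }, character(1))
  tb <- generate_quant_table(gen$db, sp, cfg, force_miss = shared)
  q <- run_quant_level(gen$db, tb, cfg, verbose = FALSE)
  expect_equal(q$summary$graphs, 16L)  # each M -> two smallest, per comparison
  expect_true(all(q$classes$protein_nodes == 1L))
})

test_that("isoform peptides stay within their base accession", {
  cfg <- fixture_config()
  sp <- synth_spec(n_components = 30L,
                   motif_mix = c(smallest = 0.5, M = 0.5),
                   isoform_rate = 0.6, seed = 53L)
  gen <- generate_database(sp, cfg)
  expect_true(length(gen$truth$isoforms) > 0)
  map <- digest_database(gen$db, cfg)
  for (iso in gen$truth$isoforms) {
    peps <- names(map$entries)[vapply(map$entries, function(a)
      iso %in% a, logical(1))]
    for (p in peps) {
      expect_length(unique(base_accession(map$entries[[p]])), 1L)
    }
  }
})

test_that("degradation report captures the two opposing effects", {
  cfg <- fixture_config()
  sp <- synth_spec(n_components = 6L, motif_mix = c(M = 1), n_states = 2L,
                   detection_prob = 1, missing_prob = 0, seed = 61L)
  gen <- generate_database(sp, cfg)
  db_comps <- components_of(gen$db, cfg)
  tb0 <- generate_quant_table(gen$db, sp, cfg)
  same <- run_quant_level(gen$db, tb0, cfg, verbose = FALSE)
  r0 <- degradation_report(db_comps, same$components)
  expect_equal(r0$delta_single_protein_graphs, 0)
  expect_equal(r0$delta_only_shared_protein_nodes, 0)
})

test_that("synthetic dataset files round-trip", {
  cfg <- fixture_config()
  sp <- synth_spec(n_components = 5L, n_states = 2L, seed = 71L)
  gen <- generate_database(sp, cfg)
  tb <- generate_quant_table(gen$db, sp, cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(gen, tb, dir)
  expect_true(all(file.exists(paths)))
  back <- read_fasta(paths[["fasta"]])
  expect_equal(back$sequence, gen$db$sequence)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth$proteins), nrow(gen$truth$proteins))
})
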