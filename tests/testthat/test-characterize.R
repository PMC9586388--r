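test_that("dataset summary counts by hand on small component sets", {
  comps <- list(m_component(), smallest_component())
  s <- summarize_dataset(comps)
  expect_equal(s$graphs, 2L)
  expect_equal(s$graphs_one_protein, 1L)
  expect_equal(s$protein_nodes, 3L)
  expect_equal(s$peptide_nodes, 4L)
  expect_equal(s$edges, 5L)
  expect_equal(s$isomorphism_classes, 2L)
  expect_equal(unname(s$largest_graph), c(2L, 3L, 4L))
  expect_equal(unname(s$second_largest_graph), c(1L, 1L, 1L))

  one <- summarize_dataset(list(smallest_component()))
  expect_equal(unname(one$largest_graph), c(1L, 1L, 1L))
  expect_equal(unname(one$second_largest_graph), c(0L, 0L, 0L))

  none <- summarize_dataset(list())
  expect_equal(none$graphs, 0L)
  expect_equal(none$protein_nodes, 0L)
  expect_equal(unname(none$largest_graph), c(0L, 0L, 0L))
})

test_that("summary totals equal sums over components", {
  sp <- random_small_spec(33L)
  comps <- components_of(generate_database(sp, fixture_config())$db)
  s <- summarize_dataset(comps)
  expect_equal(s$protein_nodes,
               sum(vapply(comps, function(cp)
                 length(cp$protein_nodes), 1L)))
  expect_equal(s$peptide_nodes,
               sum(vapply(comps, function(cp)
                 length(cp$peptide_nodes), 1L)))
  expect_equal(s$edges, sum(vapply(comps, function(cp)
    nrow(cp$edges), 1L)))
})

test_that("node count histograms bin exact counts with a 10+ tail", {
  h <- node_count_distributions(list(smallest_component(), m_component(),
                                     n_component()))
  expect_equal(h$protein_nodes[["1"]], 1 / 3)
  expect_equal(h$protein_nodes[["2"]], 2 / 3)
  hm <- node_count_distributions(list(m_component()))
  expect_equal(hm$shared_peptide_nodes[["1"]], 1)
  hs <- node_count_distributions(list(smallest_component(),
                                      smallest_component()))
  expect_equal(hs$unique_peptide_nodes[["1"]], 1)
  expect_equal(hs$shared_peptide_nodes[["0"]], 1)
  # the tail bin pools everything at or above the cap
  hub <- star_component(13, "protein")
  ht <- node_count_distributions(list(hub))
  expect_equal(ht$peptide_nodes[["10+"]], 1)
  for (v in ht) expect_equal(sum(v), 1, tolerance = 1e-9)
})

test_that("uniqueness breakdown matches the motif definitions", {
  bm <- uniqueness_breakdown(list(m_component()))
  expect_equal(bm$protein_nodes_both_pct, 100)
  expect_equal(bm$graphs_with_node_lacking_unique_pct, 0)

  bn <- uniqueness_breakdown(list(n_component()))
  expect_equal(bn$protein_nodes_only_shared_pct, 50)
  expect_equal(bn$protein_nodes_both_pct, 50)
  expect_equal(bn$graphs_with_node_lacking_unique_pct, 100)

  bw <- uniqueness_breakdown(list(w_component()))
  expect_equal(bw$protein_nodes_only_shared_pct, 100)
  expect_equal(bw$peptide_nodes_shared_pct, 100)

  smalls <- replicate(5, smallest_component(), simplify = FALSE)
  bs <- uniqueness_breakdown(smalls)
  expect_equal(bs$protein_nodes_only_unique_pct, 100)
  expect_equal(bs$peptide_nodes_shared_pct, 0)
  expect_equal(bs$graphs_with_node_lacking_unique_pct, 0)

  # percentages partition
  expect_equal(bn$peptide_nodes_unique_pct + bn$peptide_nodes_shared_pct,
               100)
  expect_equal(bn$protein_nodes_only_unique_pct + bn$protein_nodes_both_pct +
                 bn$protein_nodes_only_shared_pct, 100)
})

test_that("isoform crosstab classifies peptides at accession level", {
  cfg <- fixture_config()
  canonical <- protein_db_from_headers(
    c("P1", "P2", "P3"),
    c("AAAAKCCCCK", "DDDDKEEEEK", "DDDDKFFFFK"))
  with_iso <- protein_db_from_headers(
    c("P1", "P1-2", "P2", "P3"),
    c("AAAAKCCCCK", "AAAAKGGGGK", "DDDDKEEEEK", "DDDDKFFFFK"))
  ct <- isoform_crosstab(digest_database(canonical, cfg),
                         digest_database(with_iso, cfg))
  # AAAAK: P1 + P1-2 -> isoform-unique; unique in canonical
  expect_equal(ct["isoform_unique", "unique"], 1L)
  # GGGGK exists only in the isoform -> unique / not existing
  expect_equal(ct["unique", "not_existing"], 1L)
  # DDDDK shared between P2 and P3 in both databases
  expect_equal(ct["shared", "shared"], 1L)
  # CCCCK, EEEEK, FFFFK unique in both
  expect_equal(ct["unique", "unique"], 3L)
  expect_equal(ct["sum", "sum"], 6L)
  expect_equal(unname(ct["sum", 1:3]), unname(colSums(ct[1:3, 1:3])))
  # canonical accessions are a subset of the iso accessions, so a peptide
  # unique with isoforms can never have been shared without them
  expect_equal(ct["unique", "shared"], 0L)
  expect_equal(ct["isoform_unique", "shared"], 0L)

  expect_error(
    isoform_crosstab(digest_database(canonical, fixture_config(2L)),
                     digest_database(with_iso, cfg)),
    "digestion settings")
})

test_that("crosstab invariant holds on generated isoform databases", {
  cfg <- fixture_config()
  sp <- synth_spec(n_components = 40L,
                   motif_mix = c(smallest = 0.6, M = 0.2, N = 0.2),
                   isoform_rate = 0.5, seed = 9L)
  gen <- generate_database(sp, cfg)
  iso_db <- gen$db
  can_db <- iso_db[!grepl("-", iso_db$accession), , drop = FALSE]
  class(can_db) <- class(iso_db)
  ct <- isoform_crosstab(digest_database(can_db, cfg),
                         digest_database(iso_db, cfg))
  expect_true(length(gen$truth$isoforms) > 0)
  expect_equal(ct["unique", "shared"], 0L)
  expect_equal(ct["isoform_unique", "shared"], 0L)
  expect_equal(ct["sum", "sum"],
               length(digest_database(iso_db, cfg)$entries))
})
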