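test_that("toy grammar targets are the ordered fragment concatenation", {
  g <- toy_grammar(n_motifs = 2, seed = 1)
  motifs <- names(g$motifs)
  prot <- paste0(motifs[1], "AAAA", motifs[2], "AAAA")
  want <- paste0(g$motifs[[1]], g$motifs[[2]])
  expect_equal(smiformer:::grammar_target(prot, g), want)
  # reversed plant order reverses the fragment order
  prot_rev <- paste0(motifs[2], "AAAA", motifs[1], "AAAA")
  expect_equal(smiformer:::grammar_target(prot_rev, g),
               paste0(g$motifs[[2]], g$motifs[[1]]))
})

test_that("toy pairs are reproducible, non-empty and unambiguous", {
  g <- toy_grammar(seed = 42)
  p1 <- make_toy_pairs(g, n_pairs = 40, protein_len = 40, seed = 5)
  p2 <- make_toy_pairs(g, n_pairs = 40, protein_len = 40, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(nchar(p1$smiles) > 0))
  expect_true(all(p1$n_motifs %in% 1:3))
  # planted motifs are the only occurrences, so a motif-lookup oracle
  # reconstructs every target exactly
  for (i in seq_len(nrow(p1))) {
    expect_equal(smiformer:::grammar_target(p1$protein_sequence[i], g),
                 p1$smiles[i])
  }
})

test_that("every toy-grammar target is chemically valid", {
  g <- toy_grammar(seed = 42, validate = TRUE)
  pairs <- make_toy_pairs(g, n_pairs = 150, protein_len = 40, seed = 6)
  expect_equal(validity_rate(unique(pairs$smiles))$pct, 100)
})

test_that("the toy interaction table matches its manifest under filtering", {
  toy <- make_toy_bindingdb_table(seed = 7)
  expect_equal(nrow(toy$table), nrow(toy$manifest))
  cur <- filter_records(toy$table)
  expect_equal(nrow(cur$records), toy$n_expected_retained)
  # boundary rows: MW exactly 1000 and length exactly 80 are dropped
  expect_false(any(cur$records$mol_weight_Da >= 1000))
  expect_false(any(nchar(cur$records$protein_sequence) <= 80))
  # deterministic regeneration
  expect_identical(make_toy_bindingdb_table(seed = 7)$table, toy$table)
})

test_that("simulated score sets match their closed-form AUC manifest", {
  sim <- make_score_sets(mu_binder = -9, mu_nonbinder = -7, sigma = 1,
                         n = 2000, seed = 31)
  expect_equal(sim$manifest$expected_auc, pnorm(sqrt(2)), tolerance = 1e-12)
  r <- roc_auc(sim$scores$score[sim$scores$group == "known_binders"],
               sim$scores$score[sim$scores$group == "random"])
  expect_equal(r$auc, sim$manifest$expected_auc, tolerance = 0.03)
  # equal means -> AUC 0.5 in expectation
  flat <- make_score_sets(mu_binder = -8, mu_nonbinder = -8, sigma = 1,
                          n = 2000, seed = 32)
  expect_equal(flat$manifest$expected_auc, 0.5)
  # reproducibility
  expect_identical(make_score_sets(n = 50, seed = 9)$scores,
                   make_score_sets(n = 50, seed = 9)$scores)
  expect_error(make_score_sets(n = 1), "n >= 2")
})

test_that("fixture molecule sets deliver their manifest metrics", {
  fx <- make_fixture_molecules()
  manifest <- attr(fx, "manifest")
  expect_equal(validity_rate(fx$all_valid)$pct, manifest$all_valid$pct_valid)
  expect_equal(validity_rate(fx$all_invalid)$pct,
               manifest$all_invalid$pct_valid)
  valid_dups <- validity_rate(fx$half_duplicated)$valid
  expect_equal(uniqueness_rate(valid_dups)$pct,
               manifest$half_duplicated$pct_unique)
  dir <- withr::local_tempdir()
  paths <- write_fixture_molecules(dir)
  expect_true(all(file.exists(paths)))
  expect_equal(read_smi(paths[["all_valid"]])$smiles, fx$all_valid)
})

test_that("random protein sets are reproducible and mutually dissimilar", {
  p1 <- make_random_proteins(n = 10, len = 60, seed = 11)
  expect_identical(p1, make_random_proteins(n = 10, len = 60, seed = 11))
  expect_equal(length(unique(p1)), 10)
  id <- identity_matrix(p1[1:5])
  expect_true(all(id[upper.tri(id)] < 20))
})
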