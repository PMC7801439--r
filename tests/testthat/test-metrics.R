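test_that("validity rate counts parser-accepted strings", {
  v <- validity_rate(c("CCO", "C1CC", "c1ccccc1"))
  expect_equal(v$pct, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(v$n_total, 3)
  expect_equal(v$valid, c("CCO", "c1ccccc1"))

  fx <- make_fixture_molecules()
  expect_equal(validity_rate(fx$all_valid)$pct, 100)
  expect_equal(validity_rate(fx$all_invalid)$pct, 0)
  expect_error(validity_rate(character(0)), "empty")
})

test_that("uniqueness rate uses canonical strings and is permutation-invariant", {
  both <- canonicalize_smiles(c("CCO", "OCC"))
  expect_equal(uniqueness_rate(both)$pct, 50)
  expect_equal(uniqueness_rate(c("a", "b", "c"))$pct, 100)
  expect_equal(uniqueness_rate(rep("CCO", 4))$pct, 25)
  x <- c("CCO", "CCN", "CCO", "CCS")
  expect_equal(uniqueness_rate(x)$pct, uniqueness_rate(rev(x))$pct)
})

test_that("reference match rate handles full, zero and half overlap", {
  gen <- canonicalize_smiles(c("CCO", "CCN", "CCS", "COC"))
  expect_equal(reference_match_rate(gen, gen)$pct, 100)
  expect_equal(reference_match_rate(gen, c("c1ccccc1"))$pct, 0)
  expect_equal(reference_match_rate(gen, gen[1:2])$pct, 50)
  ref_file <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("OCC mol1", "NCC mol2"), ref_file)  # ids + non-canonical forms
  expect_equal(reference_match_rate(gen, ref_file)$pct, 50)
})

test_that("evaluation_report wires the three denominators together", {
  rep <- evaluation_report(c("CCO", "OCC", "C1CC", "CCN"),
                           reference = c("CCO"))
  expect_equal(rep$n_generated, 4)
  expect_equal(rep$pct_valid, 75)            # 3 of 4 parse
  expect_equal(rep$pct_unique, 100 * 2 / 3)  # CCO, OCC collapse
  expect_equal(rep$pct_reference_match, 50)  # of the 2 unique, CCO matches
})

test_that("property profile matches pinned chemistry-backend values", {
  prof <- property_profile(c("CC(=O)Oc1ccccc1C(=O)O", "CCO"))
  asp <- prof[1, ]
  expect_equal(asp$mol_weight_Da, 180.159, tolerance = 1e-3)
  expect_equal(asp$n_h_donors, 1L)
  expect_equal(asp$n_h_acceptors, 3L)
  expect_equal(asp$logP, 1.3101, tolerance = 1e-4)
  expect_equal(asp$tpsa_A2, 63.6, tolerance = 1e-3)
  expect_equal(asp$n_rotatable_bonds, 2L)
  expect_equal(asp$sas, 1.5800, tolerance = 1e-3)
  eth <- prof[2, ]
  expect_equal(eth$n_h_donors, 1L)
  expect_equal(eth$n_h_acceptors, 1L)
  expect_equal(eth$n_rotatable_bonds, 0L)
  expect_true(all(prof$qed >= 0 & prof$qed <= 1))
})

test_that("compliance table uses the printed strict thresholds", {
  rules <- drug_likeness_rules()
  expect_equal(rules$logP$max, 5)
  expect_equal(rules$mol_weight$max, 500)
  expect_equal(rules$h_donors$max, 5)
  expect_equal(rules$h_acceptors$max, 10)
  expect_equal(rules$rotatable_bonds$max, 10)
  expect_equal(rules$tpsa$max, 140)
  expect_equal(rules$sas$max, 6)

  fx <- make_fixture_molecules()
  prof <- property_profile(fx$logp_rule_violation)
  ct <- compliance_table(prof)
  logp_pct <- ct$table$pct_satisfying[ct$table$rule == "logP"]
  expect_equal(logp_pct, 70)  # 3 of 10 at logP >= 5 by construction
  expect_true(ct$qed$mean >= 0 && ct$qed$mean <= 1)

  asp <- compliance_table(property_profile(rep("CC(=O)Oc1ccccc1C(=O)O", 3)))
  expect_true(all(asp$table$pct_satisfying == 100))
  expect_error(compliance_table(prof, list(bad = list(property = "nope",
                                                      max = 1))), "unknown")
})

test_that("nearest-neighbor Tanimoto has the right fixed points", {
  gen <- c("CCO", "c1ccccc1")
  nn <- nearest_neighbor_tanimoto(gen, c("CCO", "c1ccccc1", "CCN"))
  expect_equal(nn$nn$nn_tanimoto, c(1, 1))  # generated subset of reference
  expect_equal(nn$mean, 1)
  # pinned benzene/toluene path-fingerprint similarity (bit-set oracle
  # |a&b|/|a|b| = 24/74)
  bt <- nearest_neighbor_tanimoto("c1ccccc1", "Cc1ccccc1")
  expect_equal(bt$nn$nn_tanimoto, 0.3243243243, tolerance = 1e-9)
  # molecules with disjoint fingerprint bit sets (alkane vs amine paths)
  zero <- nearest_neighbor_tanimoto("CCCC", "NNN")
  expect_equal(zero$nn$nn_tanimoto, 0)
  expect_error(nearest_neighbor_tanimoto("CCO", character(0)), "empty")
})

test_that("Tanimoto is symmetric for single-molecule sets", {
  withr::local_seed(12)
  fx <- make_fixture_molecules()
  mols <- fx$all_valid
  for (k in 1:5) {
    ab <- sample(mols, 2)
    s1 <- nearest_neighbor_tanimoto(ab[1], ab[2])$nn$nn_tanimoto
    s2 <- nearest_neighbor_tanimoto(ab[2], ab[1])$nn$nn_tanimoto
    expect_equal(s1, s2)
  }
})

test_that(".smi files round-trip with and without ids", {
  path <- withr::local_tempfile(fileext = ".smi")
  write_smi(c("CCO", "CCN"), path)
  got <- read_smi(path)
  expect_equal(got$smiles, c("CCO", "CCN"))
  write_smi(tibble::tibble(smiles = c("CCO", "CCN"), id = c("a", "b")), path)
  got <- read_smi(path)
  expect_equal(got$id, c("a", "b"))
})
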