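# Synthetic data generators: a learnable toy protein->SMILES grammar, toy
# BindingDB-style tables exercising every curation filter, fixture molecule
# sets with known metric values, and two-group Gaussian score samples with a
# closed-form AUC. All generators are bit-reproducible under a fixed seed.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# Fragment library: every fragment starts and ends at an atom that accepts a
# single bond, so plain concatenation of any fragments in any order yields a
# parsable molecule (verified by the chemistry backend in the test suite).
default_fragments <- function() {
  c("CCO", "CCN", "c1ccccc1", "C1CCCCC1", "CC(C)C", "COC", "CCS", "CC=CC")
}

#' Toy protein-to-SMILES grammar
#'
#' An exactly learnable translation rule standing in for real binding data:
#' each amino-acid k-mer motif maps to one SMILES fragment; a protein's
#' target molecule is the concatenation of the fragments of its planted
#' motifs, in order of occurrence. A lookup of the planted motifs therefore
#' reconstructs every target perfectly, which upper-bounds (and calibrates)
#' what the sequence model can learn.
#'
#' @param n_motifs Number of motif/fragment rules (<= number of fragments).
#' @param motif_len Motif length in residues.
#' @param fragments SMILES fragment vector (defaults to a library whose
#'   members concatenate safely); validated with the chemistry backend when
#'   `validate = TRUE`.
#' @param seed Integer seed for drawing the motifs.
#' @param validate Check fragments parse (requires the RDKit backend).
#' @return List of class `smi_grammar` with `motifs` (named character vector
#'   motif -> fragment), `motif_len`, `seed`.
#' @export
toy_grammar <- function(n_motifs = 8, motif_len = 3,
                        fragments = default_fragments(), seed = 42L,
                        validate = FALSE) {
  stopifnot(n_motifs >= 1, n_motifs <= length(fragments))
  if (validate) {
    ok <- !is.na(canonicalize_or_na(fragments))
    if (!all(ok)) {
      abort(sprintf("toy_grammar: invalid SMILES fragment '%s'.",
                    fragments[!ok][1]))
    }
  }
  motifs <- withr::with_seed(seed, {
    m <- character(0)
    while (length(m) < n_motifs) {
      cand <- paste(sample(AA20, motif_len, replace = TRUE), collapse = "")
      if (!cand %in% m) m <- c(m, cand)
    }
    m
  })
  structure(list(motifs = stats::setNames(fragments[seq_len(n_motifs)], motifs),
                 motif_len = motif_len, seed = as.integer(seed)),
            class = "smi_grammar")
}

grammar_target <- function(protein, grammar) {
  # reference translation: fragments of planted motifs in order of occurrence
  hits <- purrr::map_dfr(names(grammar$motifs), function(m) {
    starts <- gregexpr(m, protein, fixed = TRUE)[[1]]
    if (starts[1] == -1) return(NULL)
    tibble(start = as.integer(starts), fragment = grammar$motifs[[m]])
  })
  if (nrow(hits) == 0) return("")
  paste(hits$fragment[order(hits$start)], collapse = "")
}

count_motif_hits <- function(protein, motifs) {
  sum(vapply(motifs, function(m) {
    s <- gregexpr(m, protein, fixed = TRUE)[[1]]
    if (s[1] == -1) 0L else length(s)
  }, integer(1)))
}

#' Simulate paired (protein, SMILES) data from a toy grammar
#'
#' Each protein is a random residue string with 1-3 motifs planted at
#' non-overlapping positions; its target SMILES is the deterministic
#' fragment concatenation dictated by the grammar. Proteins in which any
#' motif additionally occurs by chance are rejected and redrawn, so the
#' mapping is unambiguous and every target is non-empty.
#'
#' @param grammar A [toy_grammar()].
#' @param n_pairs Number of pairs.
#' @param protein_len Protein length (>= 3 * motif length + slack).
#' @param seed Integer seed.
#' @return Tibble with columns `protein_id`, `protein_sequence`, `smiles`,
#'   `n_motifs`.
#' @export
make_toy_pairs <- function(grammar, n_pairs = 2000, protein_len = 40,
                           seed = 1L) {
  stopifnot(inherits(grammar, "smi_grammar"),
            protein_len >= 3 * grammar$motif_len)
  k <- grammar$motif_len
  motif_names <- names(grammar$motifs)
  withr::with_seed(seed, {
    out <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      repeat {
        n_m <- sample(1:3, 1)
        chosen <- sample(motif_names, n_m, replace = FALSE)
        # non-overlapping slots on a k-residue grid
        n_slots <- protein_len %/% k
        slots <- sort(sample(n_slots, n_m))
        prot <- sample(AA20, protein_len, replace = TRUE)
        for (j in seq_len(n_m)) {
          pos <- (slots[j] - 1) * k + 1
          prot[pos:(pos + k - 1)] <- strsplit(chosen[j], "")[[1]]
        }
        prot <- paste(prot, collapse = "")
        if (count_motif_hits(prot, motif_names) == n_m) break
      }
      out[[i]] <- tibble(protein_id = sprintf("toy%05d", i),
                         protein_sequence = prot,
                         smiles = grammar_target(prot, grammar),
                         n_motifs = n_m)
    }
    bind_rows(out)
  })
}

#' Toy BindingDB-style table exercising every curation filter
#'
#' Emits a raw interaction table in which specific rows fail specific
#' criteria — wrong organism, present-but-failing IC50, missing IC50 with a
#' passing Kd, EC50-only, exact boundary values for molecular weight
#' (1000 Da) and sequence length (80 and 2050), missing identifiers, an
#' unparsable SMILES, and a duplicated (protein, ligand) pair — together
#' with a manifest of the expected outcome per row.
#'
#' @param seed Integer seed (controls the random sequences used).
#' @return List with `table` (raw tibble), `manifest` (tibble `row_id`,
#'   `expect_retained`, `why`), `n_expected_retained`.
#' @export
make_toy_bindingdb_table <- function(seed = 7L) {
  rs <- function(n, s) withr::with_seed(s, paste(sample(AA20, n, TRUE), collapse = ""))
  seq_ok <- rs(120, seed)
  seq_ok2 <- rs(150, seed + 1)
  seq_len80 <- rs(80, seed + 2)
  seq_len2050 <- rs(2050, seed + 3)
  row <- function(row_id, expect, why, organism = "Homo sapiens",
                  ic50 = NA, kd = NA, ec50 = NA, mw = 300,
                  smiles = "CCO", pid = "P00001", lid = "111",
                  seqc = seq_ok) {
    tibble(row_id = row_id, expect_retained = expect, why = why,
           organism = organism, ic50_nM = ic50, kd_nM = kd, ec50_nM = ec50,
           mol_weight_Da = mw, smiles = smiles, protein_id = pid,
           ligand_id = lid, protein_sequence = seqc)
  }
  rows <- bind_rows(
    row(1, TRUE, "all criteria pass (IC50 50 nM)", ic50 = 50, smiles = "CCO"),
    row(2, FALSE, "organism not whitelisted", organism = "Danio rerio",
        ic50 = 50, smiles = "CCN"),
    row(3, FALSE, "IC50 present and >= 100 nM", ic50 = 150, smiles = "CCS"),
    row(4, TRUE, "IC50 missing, Kd 50 nM passes", kd = 50, smiles = "CCCO"),
    row(5, FALSE, "IC50 present fails although Kd would pass",
        ic50 = 500, kd = 10, smiles = "CCCN"),
    row(6, TRUE, "IC50 and Kd missing, EC50 passes", ec50 = 99,
        smiles = "CCCS", seqc = seq_ok2),
    row(7, FALSE, "all affinities missing", smiles = "CCCC"),
    row(8, FALSE, "molecular weight 1000 Da boundary (strict <)",
        ic50 = 10, mw = 1000, smiles = "CCOC"),
    row(9, FALSE, "sequence length 80 boundary (strict >)", ic50 = 10,
        smiles = "CCNC", seqc = seq_len80),
    row(10, FALSE, "sequence length 2050 boundary (strict <)", ic50 = 10,
        smiles = "COCC", seqc = seq_len2050),
    row(11, FALSE, "missing ligand identifier", ic50 = 10, lid = "",
        smiles = "CNCN"),
    row(12, FALSE, "missing protein identifier", ic50 = 10, pid = "",
        smiles = "CSCC"),
    row(13, FALSE, "unparsable SMILES", ic50 = 10, smiles = "C1CC"),
    row(14, TRUE, "valid rat record", organism = "Rattus norvegicus",
        ic50 = 1, smiles = "c1ccccc1O", seqc = seq_ok2),
    row(15, FALSE, "duplicate of row 1 after canonicalization (OCC = CCO)",
        ic50 = 60, smiles = "OCC"))
  list(table = select(rows, -"expect_retained", -"why"),
       manifest = select(rows, "row_id", "expect_retained", "why"),
       n_expected_retained = sum(rows$expect_retained))
}

#' Simulated two-group docking scores with known separation
#'
#' Draws Normal samples for a binder and a non-binder group. Under the
#' lower-is-stronger orientation the closed-form AUC of the comparison is
#' `pnorm((mu_nonbinder - mu_binder) / (sigma * sqrt(2)))`, recorded in the
#' manifest.
#'
#' @param mu_binder,mu_nonbinder Group means (e.g. kcal/mol; binders more
#'   negative).
#' @param sigma Common standard deviation (> 0).
#' @param n Sample size per group (>= 2).
#' @param seed Integer seed.
#' @return List with `scores` (tibble ligand_id, group, score) and
#'   `manifest` (list with the parameters and `expected_auc`).
#' @export
make_score_sets <- function(mu_binder = -9, mu_nonbinder = -7, sigma = 1,
                            n = 2000, seed = 1L) {
  stopifnot(sigma > 0)
  if (n < 2) abort("make_score_sets: need n >= 2 per group.")
  withr::with_seed(seed, {
    scores <- bind_rows(
      tibble(ligand_id = sprintf("bind%05d", seq_len(n)),
             group = "known_binders", score = rnorm(n, mu_binder, sigma)),
      tibble(ligand_id = sprintf("rand%05d", seq_len(n)),
             group = "random", score = rnorm(n, mu_nonbinder, sigma)))
    list(scores = scores,
         manifest = list(mu_binder = mu_binder, mu_nonbinder = mu_nonbinder,
                         sigma = sigma, n = n, seed = seed,
                         expected_auc = pnorm((mu_nonbinder - mu_binder) /
                                                (sigma * sqrt(2)))))
  })
}

#' Fixture molecule sets with known metric values
#'
#' Small named SMILES sets whose evaluation metrics are fixed by
#' construction: an all-valid set, an all-invalid set, a half-duplicated set
#' (uniqueness 50%), and a rule-violation set in which exactly 3 of 10
#' molecules have logP >= 5 (compliance 70%).
#'
#' @return List of character vectors with a `manifest` attribute recording
#'   the expected metric per set.
#' @export
make_fixture_molecules <- function() {
  all_valid <- c("CCO", "CCN", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
                 "C1CCCCC1", "CCOCC", "CC(C)CO", "c1ccncc1", "CCS", "COC")
  all_invalid <- c("C1CC", "xx", "((", "C(", "1CC")
  half_dup <- c("CCO", "CCO", "CCN", "CCN", "c1ccccc1", "c1ccccc1",
                "CCS", "CCS", "COC", "COC")
  # exactly 3 with logP >= 5: long alkanes; the rest small polar molecules
  logp_rule <- c("CCCCCCCCCCCCCCCC", "CCCCCCCCCCCCCCCCCC",
                 "CCCCCCCCCCCCCCCCCCCC",
                 "CCO", "CCN", "CO", "CCC(=O)O", "c1ccncc1", "OCC(O)CO",
                 "CC(N)C(=O)O")
  structure(list(all_valid = all_valid, all_invalid = all_invalid,
                 half_duplicated = half_dup, logp_rule_violation = logp_rule),
            manifest = list(
               all_valid = list(pct_valid = 100),
               all_invalid = list(pct_valid = 0),
               half_duplicated = list(pct_unique = 50),
               logp_rule_violation = list(n = 10, n_logp_ge_5 = 3,
                                          pct_logp_compliant = 70)))
}

#' Write the fixture sets as .smi files
#'
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths plus a JSON manifest.
#' @export
write_fixture_molecules <- function(dir) {
  fx <- make_fixture_molecules()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(fx), function(nm) {
    p <- file.path(dir, paste0(nm, ".smi"))
    writeLines(fx[[nm]], p)
    p
  }, character(1))
  jsonlite::write_json(attr(fx, "manifest"),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  paths
}

#' Random protein set for split testing
#'
#' Draws independent uniform-random amino-acid sequences; unrelated random
#' sequences of this length almost surely align well below a 20% identity
#' threshold, giving a realistic feasible input for
#' [monte_carlo_splits()].
#'
#' @param n Number of proteins.
#' @param len Sequence length.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
make_random_proteins <- function(n = 30, len = 60, seed = 11L) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
  }, character(1)))
}
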