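# Molecule-level evaluation battery: validity, uniqueness, reference-set
# match, physicochemical profiles, drug-likeness compliance and
# nearest-neighbor Tanimoto novelty. Denominator conventions (printed in
# every report): validity over all generated strings; uniqueness over valid
# canonical strings; reference match over unique valid canonical strings.

#' Validity rate of generated SMILES
#'
#' A string is valid iff the chemistry backend parses and sanitizes it.
#'
#' @param smiles_list Character vector of SMILES strings.
#' @return List with `pct` (percent valid), `n_total`, `n_valid`, and
#'   `valid` (canonical SMILES of the parsable strings, input order).
#' @export
validity_rate <- function(smiles_list) {
  stopifnot(is.character(smiles_list))
  if (length(smiles_list) == 0) abort("validity_rate: empty input list.")
  smiles_list[!nzchar(smiles_list)] <- "<empty>"  # unparsable placeholder
  canon <- canonicalize_or_na(smiles_list)
  valid <- canon[!is.na(canon)]
  list(pct = 100 * length(valid) / length(smiles_list),
       n_total = length(smiles_list), n_valid = length(valid), valid = valid)
}

#' Uniqueness rate of canonical SMILES
#'
#' @param valid_canonical_list Character vector of already-canonical SMILES.
#' @return List with `pct` = 100 * unique / total, `n_total`, `n_unique`.
#' @export
uniqueness_rate <- function(valid_canonical_list) {
  if (length(valid_canonical_list) == 0) abort("uniqueness_rate: empty input.")
  n_u <- length(unique(valid_canonical_list))
  list(pct = 100 * n_u / length(valid_canonical_list),
       n_total = length(valid_canonical_list), n_unique = n_u)
}

#' Reference-database match rate
#'
#' Percent of (unique) generated canonical SMILES found in a local reference
#' set — the stand-in for querying a large compound database such as ZINC15.
#' Both sides are canonicalized with the same backend before comparison.
#'
#' @param generated_canonical Character vector of canonical SMILES.
#' @param reference Either a character vector of SMILES or a path to a `.smi`
#'   file (one SMILES per line, optional whitespace-separated id).
#' @param canonicalize_reference Re-canonicalize the reference side (default
#'   TRUE; set FALSE if it is already canonical from the same backend).
#' @return List with `pct`, `n_unique`, `n_matched`.
#' @export
reference_match_rate <- function(generated_canonical, reference,
                                 canonicalize_reference = TRUE) {
  if (length(generated_canonical) == 0) abort("reference_match_rate: empty input.")
  if (length(reference) == 1 && file.exists(reference)) {
    reference <- read_smi(reference)$smiles
  }
  if (canonicalize_reference) {
    reference <- canonicalize_or_na(reference)
    reference <- reference[!is.na(reference)]
  }
  gen_u <- unique(generated_canonical)
  n_match <- sum(gen_u %in% reference)
  list(pct = 100 * n_match / length(gen_u),
       n_unique = length(gen_u), n_matched = n_match)
}

#' Combined validity / uniqueness / reference-match report
#'
#' The per-mode evaluation applied to a batch of generated SMILES:
#' percent valid (over all strings), percent unique (over valid canonical
#' strings) and percent matching a reference set (over unique valid
#' strings).
#'
#' @param smiles_list Generated SMILES strings.
#' @param reference Optional reference set (vector or `.smi` path).
#' @return One-row tibble of class `smi_eval_report` with columns
#'   `n_generated`, `pct_valid`, `n_valid`, `pct_unique`, `n_unique`,
#'   `pct_reference_match` (NA without a reference).
#' @export
evaluation_report <- function(smiles_list, reference = NULL) {
  v <- validity_rate(smiles_list)
  u <- if (v$n_valid > 0) uniqueness_rate(v$valid) else
    list(pct = NA_real_, n_unique = 0L)
  m <- if (!is.null(reference) && v$n_valid > 0) {
    reference_match_rate(v$valid, reference)$pct
  } else NA_real_
  out <- tibble(n_generated = v$n_total, pct_valid = v$pct,
                n_valid = v$n_valid, pct_unique = u$pct,
                n_unique = u$n_unique, pct_reference_match = m)
  class(out) <- c("smi_eval_report", class(out))
  out
}

#' Physicochemical property profile
#'
#' Computes, per molecule: logP, molecular weight (Da), hydrogen-bond donor
#' and acceptor counts, rotatable bonds, TPSA (A^2), QED and the
#' Ertl-Schuffenhauer synthetic accessibility score (SAS), via the chemistry
#' backend. Molecules the backend cannot process are kept as NA rows with a
#' warning and are excluded from summaries downstream.
#'
#' @param valid_canonical_list Character vector of valid canonical SMILES.
#' @return Tibble with column `smiles` plus the eight property columns.
#' @export
property_profile <- function(valid_canonical_list) {
  stopifnot(length(valid_canonical_list) > 0)
  raw <- rdkit_call("descriptors", valid_canonical_list)
  num <- as_tibble(lapply(raw, function(col) {
    col[!nzchar(col)] <- NA
    as.numeric(col)
  }))
  if (anyNA(num$qed)) {
    warn(sprintf("property_profile: %d molecule(s) failed in the backend; recorded as NA.",
                 sum(is.na(num$qed))))
  }
  out <- bind_cols(tibble(smiles = valid_canonical_list), num)
  out$n_h_donors <- as.integer(out$n_h_donors)
  out$n_h_acceptors <- as.integer(out$n_h_acceptors)
  out$n_rotatable_bonds <- as.integer(out$n_rotatable_bonds)
  class(out) <- c("smi_property_profile", class(out))
  out
}

#' Default drug-likeness rules
#'
#' The printed constraint set: logP < 5, MW < 500 Da, H-donors < 5,
#' H-acceptors < 10, rotatable bonds < 10, TPSA < 140 A^2, SAS < 6 (SAS > 6
#' flags molecules that are difficult to synthesize). A TPSA < 90 rule
#' (blood-brain-barrier permeation) can be added via `bbb = TRUE`.
#'
#' @param bbb Include the optional TPSA < 90 rule.
#' @return Named list of rules `(property, max)` (strict upper bounds).
#' @export
drug_likeness_rules <- function(bbb = FALSE) {
  rules <- list(
    logP = list(property = "logP", max = 5),
    mol_weight = list(property = "mol_weight_Da", max = 500),
    h_donors = list(property = "n_h_donors", max = 5),
    h_acceptors = list(property = "n_h_acceptors", max = 10),
    rotatable_bonds = list(property = "n_rotatable_bonds", max = 10),
    tpsa = list(property = "tpsa_A2", max = 140),
    sas = list(property = "sas", max = 6))
  if (bbb) rules$tpsa_bbb <- list(property = "tpsa_A2", max = 90)
  rules
}

#' Drug-likeness compliance table
#'
#' Percent of profiled molecules strictly below each rule's bound, plus the
#' mean and standard deviation of QED (which has no standard threshold).
#'
#' @param profile A [property_profile()] tibble.
#' @param rules Rule set from [drug_likeness_rules()].
#' @return List with `table` (tibble: rule, constraint, pct_satisfying, n)
#'   and `qed` (list with mean, sd, n).
#' @export
compliance_table <- function(profile, rules = drug_likeness_rules()) {
  stopifnot(nrow(profile) > 0)
  bad <- setdiff(unique(vapply(rules, `[[`, character(1), "property")),
                 names(profile))
  if (length(bad) > 0) {
    abort(sprintf("compliance_table: unknown property in rules: %s",
                  paste(bad, collapse = ", ")))
  }
  rows <- bind_rows(lapply(names(rules), function(name) {
    rl <- rules[[name]]
    x <- profile[[rl$property]]
    x <- x[!is.na(x)]
    tibble(rule = name,
           constraint = sprintf("%s < %g", rl$property, rl$max),
           pct_satisfying = 100 * mean(x < rl$max), n = length(x))
  }))
  qed <- profile$qed[!is.na(profile$qed)]
  list(table = rows,
       qed = list(mean = mean(qed), sd = stats::sd(qed), n = length(qed)))
}

#' Nearest-neighbor Tanimoto novelty
#'
#' For every generated molecule, the maximum Tanimoto fingerprint similarity
#' over a reference set (typically the training molecules). Reports the
#' distribution plus the fraction above 0.85 (conventionally "similar to a
#' known structure") and below 0.5 (substantially novel).
#'
#' @param generated,reference Character vectors of valid canonical SMILES
#'   (reference may also be a `.smi` path).
#' @param fingerprint `"path"` (2048-bit topological path fingerprint, the
#'   backend's classic default) or `"morgan"` (radius-2).
#' @param n_bits Fingerprint length.
#' @return List of class `smi_novelty`: `nn` (tibble smiles, nn_tanimoto),
#'   `mean`, `sd`, `pct_above_085`, `pct_below_05`.
#' @export
nearest_neighbor_tanimoto <- function(generated, reference,
                                      fingerprint = c("path", "morgan"),
                                      n_bits = 2048L) {
  fingerprint <- match.arg(fingerprint)
  stopifnot(length(generated) > 0)
  if (length(reference) == 1 && file.exists(reference)) {
    reference <- read_smi(reference)$smiles
  }
  if (length(reference) == 0) abort("nearest_neighbor_tanimoto: empty reference set.")
  raw <- rdkit_call("nn_tanimoto", generated, ref = reference,
                    fingerprint = fingerprint, n_bits = n_bits)
  sims <- as.numeric(ifelse(nzchar(raw$nn_tanimoto), raw$nn_tanimoto, NA))
  ok <- sims[!is.na(sims)]
  structure(list(nn = tibble(smiles = generated, nn_tanimoto = sims),
                 mean = mean(ok), sd = stats::sd(ok),
                 pct_above_085 = 100 * mean(ok > 0.85),
                 pct_below_05 = 100 * mean(ok < 0.5),
                 fingerprint = fingerprint),
            class = "smi_novelty")
}

#' @export
print.smi_novelty <- function(x, ...) {
  cat(sprintf(
    "Nearest-neighbor Tanimoto (%s fingerprint): mean %.3f, sd %.3f\n",
    x$fingerprint, x$mean, x$sd))
  cat(sprintf("  > 0.85 (similar to reference): %.1f%%   < 0.5 (novel): %.1f%%\n",
              x$pct_above_085, x$pct_below_05))
  invisible(x)
}

#' Read / write .smi files
#'
#' One SMILES per line, optionally followed by whitespace and an id.
#'
#' @param path File path.
#' @name smi_io
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  tibble(smiles = vapply(parts, `[[`, character(1), 1),
         id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                     character(1)))
}

#' @rdname smi_io
#' @param smiles Character vector (or tibble with `smiles` and optional `id`).
#' @export
write_smi <- function(smiles, path) {
  if (is.data.frame(smiles)) {
    lines <- if ("id" %in% names(smiles) && !all(is.na(smiles$id))) {
      paste(smiles$smiles, smiles$id)
    } else smiles$smiles
  } else lines <- smiles
  writeLines(lines, path)
  invisible(path)
}
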