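# Dataset curation: BindingDB-style interaction tables -> curated
# (protein, ligand) translation pairs.

# Default mapping from our canonical record fields to BindingDB-style column
# headers. Users with differently named exports override entries.
#' Default column map for BindingDB-style tables
#'
#' Named character vector mapping the canonical record fields used by
#' [filter_records()] to the column names of the input table.
#' @export
bindingdb_column_map <- function() {
  c(protein_id       = "UniProt (SwissProt) Primary ID of Target Chain",
    protein_sequence = "BindingDB Target Chain Sequence",
    ligand_id        = "PubChem CID",
    smiles           = "Ligand SMILES",
    organism         = "Target Source Organism According to Curator or DataSource",
    ic50_nM          = "IC50 (nM)",
    kd_nM            = "Kd (nM)",
    ec50_nM          = "EC50 (nM)",
    mol_weight_Da    = "Molecular Weight")
}

#' Curation filter configuration
#'
#' The record-selection rules applied by [filter_records()]. Defaults follow
#' the standard curation recipe for protein-ligand interaction tables:
#' an affinity below 100 nM with strict precedence IC50, then Kd, then EC50
#' (a later measurement is only consulted when every earlier one is missing);
#' ligand and protein identifiers present; a SMILES string present; molecular
#' weight strictly below 1000 Da; protein sequence length strictly between 80
#' and 2050 residues; and the source organism on a whitelist.
#'
#' @param affinity_max_nM Upper bound (exclusive) on the affinity, nanomolar.
#' @param mw_max_Da Upper bound (exclusive) on ligand molecular weight, Da.
#' @param seq_len_min,seq_len_max Exclusive bounds on sequence length.
#' @param organisms Character whitelist for the organism field.
#' @return A list of class `smi_filter_criteria`.
#' @export
filter_criteria <- function(affinity_max_nM = 100,
                            mw_max_Da = 1000,
                            seq_len_min = 80,
                            seq_len_max = 2050,
                            organisms = c("Homo sapiens", "Rattus norvegicus",
                                          "Mus musculus", "Bos taurus")) {
  structure(list(affinity_max_nM = affinity_max_nM, mw_max_Da = mw_max_Da,
                 seq_len_min = seq_len_min, seq_len_max = seq_len_max,
                 organisms = organisms),
            class = "smi_filter_criteria")
}

parse_affinity <- function(x) {
  # BindingDB prints qualified values like ">10000" or "<1"; treat qualified
  # or unparsable entries as missing and record them as such.
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA
  suppressWarnings(as.numeric(x))
}

#' Filter raw interaction records into a curated dataset
#'
#' Applies the seven record-selection criteria (see [filter_criteria()]) to a
#' raw BindingDB-style table, canonicalizes the SMILES of the survivors, and
#' deduplicates on (protein sequence, canonical SMILES), keeping the first
#' occurrence. Rows whose SMILES fail to parse are dropped and counted.
#'
#' @param raw_table A data frame of raw interaction rows.
#' @param criteria A [filter_criteria()] object.
#' @param column_map Named character vector mapping canonical field names to
#'   the table's column names; defaults to the package's canonical names
#'   themselves, so a pre-normalized table needs no map.
#' @return A list of class `smi_curated` with elements `records` (tibble with
#'   columns protein_id, protein_sequence, ligand_id, canonical_smiles,
#'   organism, affinity_nM, affinity_type, mol_weight_Da), `counts` (tibble of
#'   rows dropped per criterion, in application order), `unique_proteins` and
#'   `unique_smiles`.
#' @export
filter_records <- function(raw_table, criteria = filter_criteria(),
                           column_map = NULL) {
  stopifnot(is.data.frame(raw_table))
  canonical <- c("protein_id", "protein_sequence", "ligand_id", "smiles",
                 "organism", "ic50_nM", "kd_nM", "ec50_nM", "mol_weight_Da")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing_cols <- setdiff(unname(map), names(raw_table))
  if (length(missing_cols) > 0) {
    abort(sprintf("filter_records: input table lacks mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(raw_table)[, unname(map)]
  names(df) <- names(map)
  df <- mutate(df,
               across(c("protein_id", "protein_sequence", "ligand_id",
                        "smiles", "organism"), as.character),
               across(c("ic50_nM", "kd_nM", "ec50_nM", "mol_weight_Da"),
                      parse_affinity))

  n0 <- nrow(df)
  counts <- list()
  keep_step <- function(df, rule, keep) {
    counts[[rule]] <<- sum(!keep, na.rm = FALSE)
    df[keep %in% TRUE, , drop = FALSE]
  }

  df <- keep_step(df, "organism",
                  df$organism %in% criteria$organisms)
  # Affinity with strict precedence: the first *present* measurement decides.
  aff_val <- dplyr::case_when(
    !is.na(df$ic50_nM) ~ df$ic50_nM,
    !is.na(df$kd_nM) ~ df$kd_nM,
    !is.na(df$ec50_nM) ~ df$ec50_nM,
    TRUE ~ NA_real_)
  aff_type <- dplyr::case_when(
    !is.na(df$ic50_nM) ~ "IC50",
    !is.na(df$kd_nM) ~ "Kd",
    !is.na(df$ec50_nM) ~ "EC50",
    TRUE ~ NA_character_)
  df$affinity_nM <- aff_val
  df$affinity_type <- aff_type
  df <- keep_step(df, "affinity_below_max",
                  !is.na(aff_val) & aff_val >= 0 & aff_val < criteria$affinity_max_nM)
  df <- keep_step(df, "has_ligand_id",
                  !is.na(df$ligand_id) & nzchar(df$ligand_id))
  df <- keep_step(df, "has_smiles",
                  !is.na(df$smiles) & nzchar(df$smiles))
  df <- keep_step(df, "mol_weight_below_max",
                  !is.na(df$mol_weight_Da) & df$mol_weight_Da > 0 &
                    df$mol_weight_Da < criteria$mw_max_Da)
  df <- keep_step(df, "has_protein_id",
                  !is.na(df$protein_id) & nzchar(df$protein_id))
  len <- nchar(df$protein_sequence)
  df <- keep_step(df, "sequence_length_in_range",
                  !is.na(df$protein_sequence) &
                    len > criteria$seq_len_min & len < criteria$seq_len_max)

  if (nrow(df) > 0) {
    canon <- canonicalize_or_na(df$smiles)
    counts[["smiles_parsable"]] <- sum(is.na(canon))
    df$canonical_smiles <- canon
    df <- df[!is.na(canon), , drop = FALSE]
    before <- nrow(df)
    df <- distinct(df, .data$protein_sequence, .data$canonical_smiles,
                   .keep_all = TRUE)
    counts[["duplicate_pair"]] <- before - nrow(df)
  } else {
    df$canonical_smiles <- character(0)
    counts[["smiles_parsable"]] <- 0L
    counts[["duplicate_pair"]] <- 0L
  }

  records <- select(df, "protein_id", "protein_sequence", "ligand_id",
                    "canonical_smiles", "organism", "affinity_nM",
                    "affinity_type", "mol_weight_Da")
  structure(
    list(records = records,
         counts = tibble(criterion = names(counts),
                         dropped = unlist(counts, use.names = FALSE)),
         n_input = n0,
         unique_proteins = unique(records$protein_sequence),
         unique_smiles = unique(records$canonical_smiles)),
    class = "smi_curated")
}

#' @export
print.smi_curated <- function(x, ...) {
  cat(sprintf("Curated interaction dataset: %d records (from %d raw rows)\n",
              nrow(x$records), x$n_input))
  cat(sprintf("  unique proteins: %d   unique canonical SMILES: %d\n",
              length(x$unique_proteins), length(x$unique_smiles)))
  cat("  dropped per criterion:\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("    %-26s %d\n", x$counts$criterion[i], x$counts$dropped[i]))
  }
  invisible(x)
}

#' Read a BindingDB-style TSV
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with character columns.
#' @export
read_interaction_tsv <- function(path) {
  as_tibble(utils::read.delim(path, check.names = FALSE,
                              colClasses = "character", quote = ""))
}

#' Write a curated dataset as TSV
#'
#' @param curated An `smi_curated` object.
#' @param path Output file path.
#' @export
write_curated_tsv <- function(curated, path) {
  stopifnot(inherits(curated, "smi_curated"))
  utils::write.table(curated$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Tibble with columns `protein_id` and `protein_sequence`.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(protein_id = sub("\\s.*$", "", names(x)),
         protein_sequence = unname(as.character(x)))
}

#' Write protein sequences to FASTA
#'
#' @param proteins Tibble with columns `protein_id`, `protein_sequence`.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$protein_sequence)
  names(x) <- proteins$protein_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
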