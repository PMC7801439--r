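#' @useDynLib smiformer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows bind_cols
#'   left_join distinct group_by summarise ungroup n across rename
#' @importFrom generics tidy glance
#' @importFrom stats rnorm pnorm qnorm sd pwilcox
NULL

# -- RDKit bridge -------------------------------------------------------------
#
# All chemistry (SMILES parsing/canonicalization, descriptors, fingerprints)
# goes through RDKit, driven in batch via the bundled helper script so a whole
# vector of molecules costs a single interpreter start.

the <- new.env(parent = emptyenv())

rdkit_script <- function() {
  p <- system.file("python", "rdkit_tools.py", package = "smiformer")
  if (!nzchar(p)) abort("rdkit_tools.py not found; is smiformer installed?")
  p
}

find_python <- function() {
  if (!is.null(the$python)) return(the$python)
  cand <- Sys.getenv("SMIFORMER_PYTHON", unset = Sys.which("python"))
  if (!nzchar(cand)) cand <- Sys.which("python3")
  if (!nzchar(cand)) abort("No python interpreter found for the RDKit backend.")
  the$python <- cand
  cand
}

rdkit_call <- function(command, smiles, ref = NULL, fingerprint = "path",
                       n_bits = 2048L) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile)
  args <- c(rdkit_script(), command, "--in", infile, "--out", outfile)
  if (!is.null(ref)) {
    reffile <- tempfile(fileext = ".smi")
    on.exit(unlink(reffile), add = TRUE)
    writeLines(ref, reffile)
    args <- c(args, "--ref", reffile)
  }
  if (command == "nn_tanimoto") {
    args <- c(args, "--fingerprint", fingerprint, "--n-bits", n_bits)
  }
  status <- system2(find_python(), shQuote(args), stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    abort(sprintf("RDKit helper failed (command '%s', exit %s).", command, status))
  }
  lines <- readLines(outfile)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]  # line-aligned with the input; blanks mark failures
  fields <- strsplit(body, "\t", fixed = TRUE)
  out <- lapply(seq_along(header), function(j) {
    vapply(fields, function(f) if (length(f) >= j) f[j] else "", character(1))
  })
  names(out) <- header
  as_tibble(out)
}

#' Canonicalize SMILES strings with RDKit
#'
#' Maps every input string to the unique canonical SMILES RDKit emits for the
#' molecule, so that alternative writings of one structure (for example
#' `"OCC"` and `"CCO"`) collapse to a single form. Canonicalization is
#' idempotent: applying it to an already-canonical string returns the string
#' unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), any unparsable string raises an error
#'   naming the offending input; if `FALSE`, unparsable entries become `NA`.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "CCO"))  # both "CCO"
#' }
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  if (any(!nzchar(smiles) | is.na(smiles))) {
    abort("canonicalize_smiles: input contains empty or missing strings.")
  }
  out <- rdkit_call("canon", smiles)$canonical
  stopifnot(length(out) == length(smiles))
  out[is.na(out) | !nzchar(out)] <- NA_character_
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)][1]
    abort(sprintf("Invalid SMILES: '%s' cannot be parsed by the chemistry backend.", bad))
  }
  out
}

# Validity check: NA for unparsable, canonical string otherwise.
canonicalize_or_na <- function(smiles) {
  canonicalize_smiles(smiles, strict = FALSE)
}
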