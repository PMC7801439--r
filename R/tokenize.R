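# Character-level tokenization for amino-acid sequences and SMILES strings.
#
# One joint vocabulary covers both "languages": every character occurring in
# any protein sequence or SMILES string of the corpus, plus three specials.
# Two-letter element symbols (Cl, Br) deliberately become two tokens each —
# tokens are single characters. Ids: PAD = 0, BOS = 1, EOS = 2, dataset
# symbols from 3 in sorted order (PAD = 0 keeps padding masks trivial).

PAD_ID <- 0L
BOS_ID <- 1L
EOS_ID <- 2L

#' Build a joint character vocabulary from a curated dataset
#'
#' @param dataset An `smi_curated` object, or a data frame with columns
#'   `protein_sequence` and `canonical_smiles` (or `smiles`).
#' @return List of class `smi_vocab`: `tokens` (character vector indexed by
#'   id + 1, specials first), `token_to_id` (named integer vector over
#'   dataset symbols), `n_symbols` (dataset symbols, excluding specials),
#'   `size` (including specials), special ids `pad`, `bos`, `eos`.
#' @export
build_vocabulary <- function(dataset) {
  if (inherits(dataset, "smi_curated")) dataset <- dataset$records
  stopifnot(is.data.frame(dataset), nrow(dataset) > 0)
  smi_col <- intersect(c("canonical_smiles", "smiles"), names(dataset))[1]
  if (is.na(smi_col) || !"protein_sequence" %in% names(dataset)) {
    abort("build_vocabulary: need columns protein_sequence and (canonical_)smiles.")
  }
  chars <- sort(unique(unlist(strsplit(
    c(dataset$protein_sequence, dataset[[smi_col]]), ""), use.names = FALSE)))
  new_vocabulary(chars)
}

new_vocabulary <- function(symbols) {
  symbols <- sort(unique(symbols))
  specials <- c("<pad>", "<bos>", "<eos>")
  if (any(symbols %in% specials)) abort("Special token names collide with symbols.")
  tokens <- c(specials, symbols)
  structure(list(tokens = tokens,
                 token_to_id = stats::setNames(seq_along(symbols) + 2L, symbols),
                 n_symbols = length(symbols),
                 size = length(tokens),
                 pad = PAD_ID, bos = BOS_ID, eos = EOS_ID),
            class = "smi_vocab")
}

#' @export
print.smi_vocab <- function(x, ...) {
  cat(sprintf("Character vocabulary: %d symbols + 3 specials = %d tokens\n",
              x$n_symbols, x$size))
  cat(" ", paste(names(x$token_to_id), collapse = ""), "\n")
  invisible(x)
}

#' Encode a string into token ids
#'
#' @param text A single string over the vocabulary.
#' @param vocab An `smi_vocab`.
#' @param kind `"source"` (raw ids) or `"target"` (wrapped in BOS ... EOS).
#' @return Integer vector of token ids.
#' @export
encode <- function(text, vocab, kind = c("source", "target")) {
  kind <- match.arg(kind)
  stopifnot(inherits(vocab, "smi_vocab"), is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  ids <- unname(vocab$token_to_id[chars])
  bad <- which(is.na(ids))
  if (length(bad) > 0) {
    abort(sprintf("encode: character '%s' at position %d is not in the vocabulary.",
                  chars[bad[1]], bad[1]))
  }
  if (kind == "target") ids <- c(vocab$bos, ids, vocab$eos)
  as.integer(ids)
}

#' Decode token ids back to a string
#'
#' Specials (PAD/BOS/EOS) are stripped; decoding stops at the first EOS.
#'
#' @param ids Integer vector of token ids.
#' @param vocab An `smi_vocab`.
#' @return A single string.
#' @export
decode <- function(ids, vocab) {
  stopifnot(inherits(vocab, "smi_vocab"))
  ids <- as.integer(ids)
  eos_at <- which(ids == vocab$eos)
  if (length(eos_at) > 0) ids <- ids[seq_len(eos_at[1] - 1)]
  ids <- ids[!(ids %in% c(vocab$pad, vocab$bos, vocab$eos))]
  if (any(ids < 0 | ids >= vocab$size)) abort("decode: id out of vocabulary range.")
  paste(vocab$tokens[ids + 1L], collapse = "")
}

#' Pad a batch of token sequences
#'
#' @param seqs List of integer id vectors.
#' @param max_len Width of the padded matrix; defaults to the longest
#'   sequence. Sequences longer than `max_len` are an error.
#' @return List with `ids` (n x max_len integer matrix, PAD-filled) and
#'   `mask` (logical matrix, `TRUE` exactly on real token positions).
#' @export
pad_batch <- function(seqs, max_len = NULL) {
  stopifnot(is.list(seqs), length(seqs) > 0)
  lens <- lengths(seqs)
  if (is.null(max_len)) max_len <- max(lens)
  if (any(lens > max_len)) {
    abort(sprintf("pad_batch: sequence of length %d exceeds max_len %d.",
                  max(lens), max_len))
  }
  ids <- matrix(PAD_ID, nrow = length(seqs), ncol = max_len)
  mask <- matrix(FALSE, nrow = length(seqs), ncol = max_len)
  for (i in seq_along(seqs)) {
    if (lens[i] > 0) {
      ids[i, seq_len(lens[i])] <- seqs[[i]]
      mask[i, seq_len(lens[i])] <- TRUE
    }
  }
  list(ids = ids, mask = mask)
}

#' Undo [pad_batch()]
#'
#' @param padded List with `ids` and `mask` as returned by [pad_batch()].
#' @return List of integer vectors.
#' @export
unpad_batch <- function(padded) {
  lapply(seq_len(nrow(padded$ids)), function(i) {
    as.integer(padded$ids[i, padded$mask[i, ]])
  })
}

#' Write / read a vocabulary as a token-per-line text file
#'
#' @param vocab An `smi_vocab`.
#' @param path File path.
#' @name vocab_io
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(c("# smiformer vocabulary v1", vocab$tokens), path)
  invisible(path)
}

#' @rdname vocab_io
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "# smiformer vocabulary v1")) {
    abort("read_vocabulary: unrecognized vocabulary file header.")
  }
  tokens <- lines[-1]
  new_vocabulary(tokens[-(1:3)])
}

vocab_hash <- function(vocab) {
  # Order-sensitive polynomial content hash over the token list; guards
  # checkpoints against being resumed with a different vocabulary.
  s <- paste(vocab$tokens, collapse = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%d", h)
}
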