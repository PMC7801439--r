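# Beam-search decoding.
#
# The search is written against an abstract scoring function so the same code
# decodes the fitted transformer and the tiny tabulated models used to test
# it against exhaustive enumeration. Scores are summed token log-probs; an
# optional GNMT-style length penalty is available but off by default. Ties
# break toward the lower token id (then the earlier hypothesis), which makes
# decoding fully deterministic.

#' Beam search over an autoregressive scoring function
#'
#' At each step every live hypothesis is extended by every vocabulary token;
#' the `beam_size` best extensions by cumulative log-probability survive. A
#' hypothesis finishes when it emits EOS (its EOS log-prob is included in the
#' score) or reaches `max_len` tokens. With `beam_size = 1` the search is
#' greedy; with `beam_size >= vocab_size^max_len` it is exhaustive.
#'
#' @param step_fn Function taking an integer matrix of prefixes (one row per
#'   hypothesis, starting with BOS) and returning a matrix of log-probability
#'   rows over the vocabulary (ids 0 .. vocab_size-1 in column order).
#' @param vocab_size Total vocabulary size including specials.
#' @param bos_id,eos_id Special token ids.
#' @param beam_size Number of hypotheses kept per step (>= 1).
#' @param max_len Maximum generated tokens (excluding BOS/EOS).
#' @param length_penalty GNMT alpha; 0 (default) ranks by raw summed
#'   log-prob.
#' @param forbid_ids Token ids never proposed (default: BOS and PAD = 0).
#' @return Tibble of class `smi_beam` with columns `ids` (list of integer
#'   vectors, specials excluded), `logprob`, `finished`, sorted by descending
#'   (penalized) score.
#' @export
beam_search <- function(step_fn, vocab_size, bos_id = 1L, eos_id = 2L,
                        beam_size = 4L, max_len = 202L, length_penalty = 0,
                        forbid_ids = c(0L, bos_id)) {
  if (beam_size < 1) abort("beam_search: beam_size must be >= 1.")
  if (max_len < 1) abort("beam_search: max_len must be >= 1.")
  live_prefix <- matrix(as.integer(bos_id), nrow = 1)
  live_score <- 0
  done_ids <- list(); done_score <- numeric(0)

  for (t in seq_len(max_len + 1L)) {
    lp <- step_fn(live_prefix)
    if (!is.matrix(lp) || ncol(lp) != vocab_size || nrow(lp) != nrow(live_prefix)) {
      abort("beam_search: step_fn must return one log-prob row per hypothesis.")
    }
    cand_score <- sweep(lp, 1, live_score, `+`)
    cand_score[, forbid_ids + 1L] <- -Inf
    at_cap <- ncol(live_prefix) - 1L >= max_len
    if (at_cap) {  # only EOS may be proposed at the length cap
      keep_eos <- cand_score[, eos_id + 1L]
      cand_score[] <- -Inf
      cand_score[, eos_id + 1L] <- keep_eos
    }
    flat <- data.frame(hyp = rep(seq_len(nrow(lp)), times = vocab_size),
                       tok = rep(seq_len(vocab_size) - 1L, each = nrow(lp)),
                       score = as.vector(cand_score))
    flat <- flat[is.finite(flat$score), , drop = FALSE]
    if (nrow(flat) == 0) {
      # no continuation scores finitely: finalize live hypotheses as-is
      for (i in seq_len(nrow(live_prefix))) {
        done_ids[[length(done_ids) + 1]] <- live_prefix[i, -1]
        done_score <- c(done_score, live_score[i])
      }
      break
    }
    flat <- flat[order(-flat$score, flat$tok, flat$hyp), , drop = FALSE]
    flat <- utils::head(flat, beam_size)

    new_prefix <- NULL; new_score <- numeric(0)
    for (r in seq_len(nrow(flat))) {
      seq_ids <- c(live_prefix[flat$hyp[r], ], flat$tok[r])
      if (flat$tok[r] == eos_id) {
        done_ids[[length(done_ids) + 1]] <- seq_ids[-c(1, length(seq_ids))]
        done_score <- c(done_score, flat$score[r])
      } else {
        new_prefix <- rbind(new_prefix, seq_ids)
        new_score <- c(new_score, flat$score[r])
      }
    }
    if (is.null(new_prefix)) break
    # beam is full once enough finished hypotheses outscore all live ones
    if (length(done_score) >= beam_size &&
        max(new_score) <= sort(done_score, decreasing = TRUE)[beam_size]) break
    live_prefix <- new_prefix
    rownames(live_prefix) <- NULL
    live_score <- new_score
  }
  if (length(done_ids) == 0) {
    for (i in seq_len(nrow(live_prefix))) {
      done_ids[[length(done_ids) + 1]] <- live_prefix[i, -1]
      done_score <- c(done_score, live_score[i])
    }
  }
  penalized <- if (length_penalty > 0) {
    done_score / (((5 + lengths(done_ids)) / 6)^length_penalty)
  } else done_score
  ord <- order(-penalized)
  out <- tibble(ids = done_ids[ord], logprob = done_score[ord],
                penalized = penalized[ord],
                finished = TRUE)[seq_len(min(beam_size, length(ord))), ]
  class(out) <- c("smi_beam", class(out))
  out
}

model_step_fn <- function(model, src_ids, memory) {
  force(memory)
  cfg <- cfg_for_cpp(model$config, model$vocab)
  flat <- flatten_weights(model$weights)
  function(prefixes) {
    cpp_decode_logprobs(flat, cfg, memory, prefixes, src_ids)
  }
}

encode_protein <- function(model, protein) {
  src_ids <- encode(protein, model$vocab, kind = "source")
  if (length(src_ids) > model$config$max_source_len) {
    abort(sprintf("Protein length %d exceeds max_source_len %d.",
                  length(src_ids), model$config$max_source_len))
  }
  list(src_ids = src_ids,
       memory = cpp_encode(flatten_weights(model$weights),
                           cfg_for_cpp(model$config, model$vocab), src_ids))
}

#' Greedy decoding of one protein
#'
#' Beam search with beam size 1 (argmax decoding).
#'
#' @param model A fitted `smi_model`.
#' @param protein Amino-acid sequence.
#' @return The decoded SMILES string.
#' @export
greedy_decode <- function(model, protein) {
  enc <- encode_protein(model, protein)
  beam <- beam_search(model_step_fn(model, enc$src_ids, enc$memory),
                      vocab_size = model$vocab$size, beam_size = 1L,
                      max_len = model$config$max_target_len)
  decode(beam$ids[[1]], model$vocab)
}

#' Generate molecules for a target protein
#'
#' Runs beam-search decoding of the fitted model on one protein sequence.
#' `"one_per_one"` mode decodes with beam size 4 and returns only the single
#' highest-probability SMILES; `"ten_per_one"` decodes with beam size 10 and
#' returns all ten candidates (fewer if distinct hypotheses collapse to the
#' same detokenized string).
#'
#' @param model A fitted `smi_model`.
#' @param protein Amino-acid sequence (single string).
#' @param mode `"one_per_one"` or `"ten_per_one"`.
#' @param protein_id Identifier copied into the result (defaults to the
#'   sequence itself, truncated).
#' @param length_penalty Passed to [beam_search()].
#' @return Tibble with columns `protein_id`, `rank`, `smiles`, `logprob`,
#'   `mode`; log-probabilities are non-increasing in rank.
#' @export
generate <- function(model, protein, mode = c("one_per_one", "ten_per_one"),
                     protein_id = NULL, length_penalty = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "smi_model"))
  if (is.null(protein_id)) protein_id <- substr(protein, 1, 12)
  beam_size <- if (mode == "one_per_one") 4L else 10L
  enc <- encode_protein(model, protein)
  beam <- beam_search(model_step_fn(model, enc$src_ids, enc$memory),
                      vocab_size = model$vocab$size, beam_size = beam_size,
                      max_len = model$config$max_target_len,
                      length_penalty = length_penalty)
  smi <- vapply(beam$ids, decode, character(1), vocab = model$vocab)
  out <- tibble(protein_id = protein_id, smiles = smi,
                logprob = beam$logprob, mode = mode)
  out <- out[!duplicated(out$smiles), ]
  if (mode == "one_per_one") out <- out[1, ]
  out$rank <- seq_len(nrow(out))
  select(out, "protein_id", "rank", "smiles", "logprob", "mode")
}

#' Generate for every protein in a table
#'
#' @param model A fitted `smi_model`.
#' @param proteins Data frame with `protein_id` and `protein_sequence`
#'   columns (e.g. from [read_protein_fasta()]).
#' @inheritParams generate
#' @return Row-bound [generate()] results.
#' @export
generate_all <- function(model, proteins,
                         mode = c("one_per_one", "ten_per_one"),
                         length_penalty = 0) {
  mode <- match.arg(mode)
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    generate(model, proteins$protein_sequence[i], mode = mode,
             protein_id = proteins$protein_id[i],
             length_penalty = length_penalty)
  })
}
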