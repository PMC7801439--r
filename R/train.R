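# Training driver: tokenize pairs, bucket into token-count batches, run the
# compiled optimizer loop, and wrap the result as a fitted model object.

as_row <- function(v) matrix(v, nrow = 1)

# Flat parameter order consumed by the compiled engine. Biases and layer-norm
# parameters travel as 1-row matrices.
flatten_weights <- function(w) {
  out <- list(src_emb = w$src_emb, tgt_emb = w$tgt_emb,
              out_W = w$out_W, out_b = as_row(w$out_b))
  for (l in seq_along(w$enc)) {
    e <- w$enc[[l]]
    out[paste0("enc", l, ".", c("Wq", "Wk", "Wv", "Wo", "ln1g", "ln1b", "W1",
                                "b1", "W2", "b2", "ln2g", "ln2b"))] <-
      list(e$attn$Wq, e$attn$Wk, e$attn$Wv, e$attn$Wo,
           as_row(e$ln1$g), as_row(e$ln1$b),
           e$ffn$W1, as_row(e$ffn$b1), e$ffn$W2, as_row(e$ffn$b2),
           as_row(e$ln2$g), as_row(e$ln2$b))
  }
  for (l in seq_along(w$dec)) {
    d <- w$dec[[l]]
    out[paste0("dec", l, ".",
               c("sWq", "sWk", "sWv", "sWo", "ln1g", "ln1b",
                 "cWq", "cWk", "cWv", "cWo", "ln2g", "ln2b",
                 "W1", "b1", "W2", "b2", "ln3g", "ln3b"))] <-
      list(d$self$Wq, d$self$Wk, d$self$Wv, d$self$Wo,
           as_row(d$ln1$g), as_row(d$ln1$b),
           d$cross$Wq, d$cross$Wk, d$cross$Wv, d$cross$Wo,
           as_row(d$ln2$g), as_row(d$ln2$b),
           d$ffn$W1, as_row(d$ffn$b1), d$ffn$W2, as_row(d$ffn$b2),
           as_row(d$ln3$g), as_row(d$ln3$b))
  }
  out[c("final.enc_lng", "final.enc_lnb", "final.dec_lng", "final.dec_lnb")] <-
    list(as_row(w$enc_final_ln$g), as_row(w$enc_final_ln$b),
         as_row(w$dec_final_ln$g), as_row(w$dec_final_ln$b))
  out
}

unflatten_weights <- function(flat, config) {
  g <- function(nm) flat[[nm]]
  v <- function(nm) as.numeric(flat[[nm]])
  w <- list(src_emb = g("src_emb"), tgt_emb = g("tgt_emb"),
            out_W = g("out_W"), out_b = v("out_b"),
            enc = lapply(seq_len(config$n_layers), function(l) {
              p <- function(s) paste0("enc", l, ".", s)
              list(attn = list(Wq = g(p("Wq")), Wk = g(p("Wk")),
                               Wv = g(p("Wv")), Wo = g(p("Wo"))),
                   ln1 = list(g = v(p("ln1g")), b = v(p("ln1b"))),
                   ffn = list(W1 = g(p("W1")), b1 = v(p("b1")),
                              W2 = g(p("W2")), b2 = v(p("b2"))),
                   ln2 = list(g = v(p("ln2g")), b = v(p("ln2b"))))
            }),
            dec = lapply(seq_len(config$n_layers), function(l) {
              p <- function(s) paste0("dec", l, ".", s)
              list(self = list(Wq = g(p("sWq")), Wk = g(p("sWk")),
                               Wv = g(p("sWv")), Wo = g(p("sWo"))),
                   ln1 = list(g = v(p("ln1g")), b = v(p("ln1b"))),
                   cross = list(Wq = g(p("cWq")), Wk = g(p("cWk")),
                                Wv = g(p("cWv")), Wo = g(p("cWo"))),
                   ln2 = list(g = v(p("ln2g")), b = v(p("ln2b"))),
                   ffn = list(W1 = g(p("W1")), b1 = v(p("b1")),
                              W2 = g(p("W2")), b2 = v(p("b2"))),
                   ln3 = list(g = v(p("ln3g")), b = v(p("ln3b"))))
            }),
            enc_final_ln = list(g = v("final.enc_lng"), b = v("final.enc_lnb")),
            dec_final_ln = list(g = v("final.dec_lng"), b = v("final.dec_lnb")))
  structure(w, class = "smi_weights", vocab_size = nrow(flat$src_emb))
}

cfg_for_cpp <- function(config, vocab) {
  c(unclass(config), list(vocab_size = vocab$size))
}

# Token-count batching: sort pairs by target length, slice into batches whose
# source+target token total stays under batch_tokens, pad within batch.
make_batches <- function(pairs, vocab, batch_tokens) {
  src <- lapply(pairs$protein_sequence, encode, vocab = vocab, kind = "source")
  tgt <- lapply(pairs$smiles, encode, vocab = vocab, kind = "target")
  ord <- order(lengths(tgt), lengths(src))
  batches <- list()
  i <- 1
  while (i <= length(ord)) {
    j <- i
    tok <- 0
    repeat {
      tok_j <- length(src[[ord[j]]]) + length(tgt[[ord[j]]])
      if (j > i && tok + tok_j > batch_tokens) break
      tok <- tok + tok_j
      if (j == length(ord)) break
      j <- j + 1
      if (tok >= batch_tokens) break
    }
    if (tok + length(src[[ord[j]]]) + length(tgt[[ord[j]]]) > batch_tokens && j > i) j <- j - 1
    idx <- ord[i:j]
    sp <- pad_batch(src[idx])
    tp <- pad_batch(tgt[idx])
    tgt_in <- tp$ids[, -ncol(tp$ids), drop = FALSE]
    tgt_out <- tp$ids[, -1, drop = FALSE]
    batches[[length(batches) + 1]] <-
      list(src = sp$ids, tgt_in = tgt_in, tgt_out = tgt_out)
    i <- j + 1
  }
  batches
}

#' Train the protein-to-SMILES transformer
#'
#' Teacher-forced training of the encoder-decoder transformer on curated
#' (protein, SMILES) pairs with label-smoothed cross entropy, the Adam
#' optimizer and the inverse-square-root warmup learning-rate schedule
#' ([lr_schedule()]). Fully deterministic under `seed` on a single device.
#'
#' @param pairs Data frame with columns `protein_sequence` and `smiles` (or
#'   `canonical_smiles`).
#' @param config A [model_config()].
#' @param steps Number of optimizer steps.
#' @param batch_tokens Approximate tokens (source + target) per batch.
#' @param seed Integer seed controlling initialization, batch order and
#'   dropout.
#' @param vocab Optional [build_vocabulary()] result; built from `pairs`
#'   otherwise.
#' @param init Optional fitted `smi_model` to resume from; its weights,
#'   optimizer moments and step counter continue seamlessly, and the
#'   vocabulary hash must match.
#' @param log_every Record (step, lr, loss) every this many steps.
#' @param single_precision Run the compiled engine in single precision
#'   (default; roughly twice as fast) or in double precision.
#' @return An object of class `smi_model`: weights, config, vocab, training
#'   log (tibble), optimizer state and step counter.
#' @export
train_model <- function(pairs, config = model_config(), steps = 1000,
                        batch_tokens = 4096, seed = 1L, vocab = NULL,
                        init = NULL, log_every = 25,
                        single_precision = TRUE) {
  if (inherits(pairs, "smi_curated")) pairs <- pairs$records
  if (!"smiles" %in% names(pairs) && "canonical_smiles" %in% names(pairs)) {
    pairs <- rename(pairs, smiles = "canonical_smiles")
  }
  stopifnot(all(c("protein_sequence", "smiles") %in% names(pairs)),
            nrow(pairs) > 0, steps >= 1)
  if (is.null(vocab)) vocab <- build_vocabulary(
    tibble(protein_sequence = pairs$protein_sequence,
           canonical_smiles = pairs$smiles))

  if (!is.null(init)) {
    stopifnot(inherits(init, "smi_model"))
    if (!identical(vocab_hash(init$vocab), vocab_hash(vocab))) {
      abort("train_model: checkpoint vocabulary does not match the data vocabulary.")
    }
    config <- init$config
    flat <- flatten_weights(init$weights)
    adam_m <- init$optimizer$m
    adam_v <- init$optimizer$v
    step_start <- init$step + 1L
  } else {
    flat <- flatten_weights(init_weights(config, vocab$size, seed = seed))
    adam_m <- NULL
    adam_v <- NULL
    step_start <- 1L
  }

  batches <- make_batches(pairs, vocab, batch_tokens)
  n_b <- length(batches)
  # seeded batch order: reshuffled every pass, deterministic, resume-safe
  schedule <- withr::with_seed(seed + 7L, {
    full <- unlist(lapply(seq_len(ceiling((step_start + steps) / n_b)),
                          function(e) sample.int(n_b)))
    full[step_start:(step_start + steps - 1L)]
  })

  fit <- cpp_train(flat, cfg_for_cpp(config, vocab), batches, schedule,
                   step_start, adam_m, adam_v, as.integer(seed), log_every,
                   single_precision)

  structure(list(weights = unflatten_weights(fit$params, config),
                 config = config, vocab = vocab,
                 log = bind_rows(if (!is.null(init)) init$log,
                                 as_tibble(fit$log)),
                 optimizer = list(m = fit$m, v = fit$v),
                 step = step_start + as.integer(steps) - 1L,
                 vocab_hash = vocab_hash(vocab), seed = as.integer(seed)),
            class = "smi_model")
}

#' @export
print.smi_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Protein-to-SMILES transformer: %d layers, d_model %d, %d heads, vocab %d\n",
    cfg$n_layers, cfg$d_model, cfg$n_heads, x$vocab$size))
  cat(sprintf("  trained %d steps; final training loss %.4f\n",
              x$step, utils::tail(x$log$loss, 1)))
  invisible(x)
}

#' @export
tidy.smi_model <- function(x, ...) x$log

#' @export
glance.smi_model <- function(x, ...) {
  n_par <- sum(vapply(flatten_weights(x$weights), length, numeric(1)))
  tibble(n_layers = x$config$n_layers, d_model = x$config$d_model,
         n_heads = x$config$n_heads, n_parameters = n_par,
         steps = x$step, final_loss = utils::tail(x$log$loss, 1))
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, configuration, vocabulary (with content
#' hash), optimizer state and the step counter, so training can resume and
#' resumption refuses a mismatched vocabulary.
#'
#' @param model An `smi_model`.
#' @param path File path (`.rds`).
#' @name checkpoint
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "smi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "smi_model"))
  if (!identical(model$vocab_hash, vocab_hash(model$vocab))) {
    abort("load_checkpoint: vocabulary hash mismatch; checkpoint corrupted.")
  }
  model
}

#' Held-out exact-match accuracy of greedy decoding
#'
#' Greedy-decodes every protein and scores an exact string match against the
#' paired reference SMILES.
#'
#' @param model A fitted `smi_model`.
#' @param pairs Data frame with `protein_sequence` and `smiles`.
#' @return Fraction in \[0, 1\]; per-protein results attached as attribute
#'   `"details"`.
#' @export
exact_match_accuracy <- function(model, pairs) {
  if (!"smiles" %in% names(pairs) && "canonical_smiles" %in% names(pairs)) {
    pairs <- rename(pairs, smiles = "canonical_smiles")
  }
  dec <- vapply(pairs$protein_sequence, function(p) {
    greedy_decode(model, p)
  }, character(1), USE.NAMES = FALSE)
  hit <- dec == pairs$smiles
  structure(mean(hit),
            details = tibble(protein_sequence = pairs$protein_sequence,
                             reference = pairs$smiles, decoded = dec,
                             match = hit))
}
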