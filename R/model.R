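# Model configuration, weight initialization and the reference R forward
# pass. The training loop itself lives in compiled code (src/transformer.cpp)
# and consumes exactly the weight layout defined here.

#' Transformer hyperparameter set
#'
#' @param n_layers Encoder and decoder depth (default 4).
#' @param d_model Embedding / residual width (default 128).
#' @param n_heads Attention heads (default 4); must divide `d_model`.
#' @param d_ff Feed-forward inner width; default `4 * d_model`.
#' @param dropout Dropout rate in \[0, 1); applied after embeddings and each
#'   sublayer during training only.
#' @param pe_base Positional-encoding base (default 10000).
#' @param label_smoothing Cross-entropy label smoothing (default 0.1).
#' @param warmup_steps Warmup horizon of the learning-rate schedule.
#' @param max_source_len,max_target_len Hard length caps on protein and
#'   SMILES token sequences (target cap excludes BOS/EOS).
#' @param norm_position Where layer normalization sits relative to each
#'   sublayer: `"pre"` (default; normalize-then-sublayer with a final layer
#'   norm, markedly easier to optimize at small step budgets) or `"post"`
#'   (sublayer-then-normalize, the classic composition).
#' @return List of class `smi_config`.
#' @export
model_config <- function(n_layers = 4, d_model = 128, n_heads = 4,
                         d_ff = 4 * d_model, dropout = 0.1, pe_base = 10000,
                         label_smoothing = 0.1, warmup_steps = 4000,
                         max_source_len = 2050, max_target_len = 200,
                         norm_position = c("pre", "post")) {
  norm_position <- match.arg(norm_position)
  if (d_model %% n_heads != 0) abort("model_config: d_model must be divisible by n_heads.")
  if (d_model %% 2 != 0) abort("model_config: d_model must be even.")
  stopifnot(n_layers >= 0, d_ff > 0, dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 dropout = dropout, pe_base = pe_base,
                 label_smoothing = label_smoothing,
                 warmup_steps = as.integer(warmup_steps),
                 max_source_len = as.integer(max_source_len),
                 max_target_len = as.integer(max_target_len),
                 norm_position = norm_position),
            class = "smi_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

attn_block <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d), Wo = glorot(d, d))
}

ffn_block <- function(d, d_ff) {
  list(W1 = glorot(d, d_ff), b1 = numeric(d_ff), W2 = glorot(d_ff, d),
       b2 = numeric(d))
}

ln_block <- function(d) list(g = rep(1, d), b = numeric(d))

#' Initialize transformer weights
#'
#' Glorot-uniform initialization, deterministic under the seed. Source and
#' target embeddings are untied.
#'
#' @param config An [model_config()].
#' @param vocab_size Vocabulary size including specials.
#' @param seed Integer seed.
#' @return Nested list of weight matrices (class `smi_weights`).
#' @export
init_weights <- function(config, vocab_size, seed = 1L) {
  withr::with_seed(seed, {
    d <- config$d_model
    w <- list(
      src_emb = glorot(vocab_size, d),
      tgt_emb = glorot(vocab_size, d),
      out_W = glorot(d, vocab_size),
      out_b = numeric(vocab_size),
      enc = lapply(seq_len(config$n_layers), function(l) {
        list(attn = attn_block(d), ln1 = ln_block(d),
             ffn = ffn_block(d, config$d_ff), ln2 = ln_block(d))
      }),
      dec = lapply(seq_len(config$n_layers), function(l) {
        list(self = attn_block(d), ln1 = ln_block(d),
             cross = attn_block(d), ln2 = ln_block(d),
             ffn = ffn_block(d, config$d_ff), ln3 = ln_block(d))
      }),
      enc_final_ln = ln_block(d),
      dec_final_ln = ln_block(d))
    structure(w, class = "smi_weights", vocab_size = vocab_size)
  })
}

embed_ids <- function(ids, emb, pe, d_model) {
  x <- emb[ids + 1L, , drop = FALSE] * sqrt(d_model)
  x + pe[seq_along(ids), , drop = FALSE]
}

#' Encoder forward pass (reference implementation)
#'
#' Embeds a source token sequence, adds positional encodings, and applies
#' `n_layers` of multi-head self-attention and position-wise feed-forward
#' sublayers, each followed by a residual connection and layer normalization.
#' Deterministic (inference mode; no dropout).
#'
#' @param src_ids Integer vector of source token ids (no padding).
#' @param weights An `smi_weights` object.
#' @param config The matching [model_config()].
#' @return Context matrix z, `length(src_ids)` x `d_model`.
#' @export
encoder_forward <- function(src_ids, weights, config) {
  n <- length(src_ids)
  if (n == 0) abort("encoder_forward: empty source sequence.")
  if (n > config$max_source_len) {
    abort(sprintf("encoder_forward: source length %d exceeds cap %d.",
                  n, config$max_source_len))
  }
  pe <- positional_encoding(n, config$d_model, config$pe_base)
  x <- embed_ids(src_ids, weights$src_emb, pe, config$d_model)
  pre <- identical(config$norm_position, "pre")
  for (layer in weights$enc) {
    if (pre) {
      xn <- layer_norm(x, layer$ln1$g, layer$ln1$b)
      x <- x + multihead_attention(xn, xn, xn, layer$attn,
                                   config$n_heads)$output
      xn <- layer_norm(x, layer$ln2$g, layer$ln2$b)
      x <- x + ffn_apply(xn, layer$ffn, n)
    } else {
      a <- multihead_attention(x, x, x, layer$attn, config$n_heads)$output
      x <- layer_norm(x + a, layer$ln1$g, layer$ln1$b)
      x <- layer_norm(x + ffn_apply(x, layer$ffn, n),
                      layer$ln2$g, layer$ln2$b)
    }
  }
  if (pre) x <- layer_norm(x, weights$enc_final_ln$g, weights$enc_final_ln$b)
  x
}

ffn_apply <- function(x, ffn, n) {
  relu(x %*% ffn$W1 + rep_row(ffn$b1, n)) %*% ffn$W2 + rep_row(ffn$b2, n)
}

relu <- function(x) pmax(x, 0)
rep_row <- function(b, n) matrix(b, n, length(b), byrow = TRUE)

#' Decoder forward pass (reference implementation)
#'
#' Runs the decoder over a target prefix with a causal self-attention mask
#' (position t attends only to positions <= t) and cross-attention to the
#' encoder context, and returns a probability distribution over the
#' vocabulary for every prefix position.
#'
#' @param tgt_ids Integer vector of target token ids (starting with BOS).
#' @param context Context matrix from [encoder_forward()].
#' @param weights,config Model weights and configuration.
#' @return `length(tgt_ids)` x vocab matrix; each row is a probability
#'   distribution (rows sum to 1).
#' @export
decoder_forward <- function(tgt_ids, context, weights, config) {
  m <- length(tgt_ids)
  if (m == 0) abort("decoder_forward: empty target prefix.")
  if (ncol(context) != config$d_model) {
    abort("decoder_forward: context width does not match d_model.")
  }
  pe <- positional_encoding(m, config$d_model, config$pe_base)
  y <- embed_ids(tgt_ids, weights$tgt_emb, pe, config$d_model)
  causal <- lower.tri(matrix(TRUE, m, m), diag = TRUE)
  pre <- identical(config$norm_position, "pre")
  for (layer in weights$dec) {
    if (pre) {
      yn <- layer_norm(y, layer$ln1$g, layer$ln1$b)
      y <- y + multihead_attention(yn, yn, yn, layer$self, config$n_heads,
                                   mask = causal)$output
      yn <- layer_norm(y, layer$ln2$g, layer$ln2$b)
      y <- y + multihead_attention(yn, context, context, layer$cross,
                                   config$n_heads)$output
      yn <- layer_norm(y, layer$ln3$g, layer$ln3$b)
      y <- y + ffn_apply(yn, layer$ffn, m)
    } else {
      a <- multihead_attention(y, y, y, layer$self, config$n_heads,
                               mask = causal)$output
      y <- layer_norm(y + a, layer$ln1$g, layer$ln1$b)
      cr <- multihead_attention(y, context, context, layer$cross,
                                config$n_heads)$output
      y <- layer_norm(y + cr, layer$ln2$g, layer$ln2$b)
      y <- layer_norm(y + ffn_apply(y, layer$ffn, m),
                      layer$ln3$g, layer$ln3$b)
    }
  }
  if (pre) y <- layer_norm(y, weights$dec_final_ln$g, weights$dec_final_ln$b)
  logits <- y %*% weights$out_W + rep_row(weights$out_b, m)
  softmax_rows(logits)
}

#' Learning-rate schedule
#'
#' The inverse-square-root warmup schedule:
#' `lr(step) = d_model^-0.5 * min(step^-0.5, step * warmup^-1.5)`.
#'
#' @param step Optimizer step (>= 1), vectorized.
#' @param d_model Model width.
#' @param warmup_steps Warmup horizon.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(step, d_model, warmup_steps) {
  d_model^(-0.5) * pmin(step^(-0.5), step * warmup_steps^(-1.5))
}
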