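# Attention primitives.
#
# These are the mathematical building blocks of the model, written plainly in
# R. The compiled training engine re-implements the same arithmetic; a test
# asserts the two agree, so these functions double as the reference
# definition of the forward pass.

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`, masking out disallowed key
#' positions before the softmax. Each output row is a convex combination of
#' the rows of `V`.
#'
#' @param Q Query matrix, m x d_k.
#' @param K Key matrix, n x d_k.
#' @param V Value matrix, n x d_v.
#' @param mask Optional logical m x n matrix; `TRUE` marks positions a query
#'   may attend to. A fully masked row is an error (the softmax would be
#'   undefined).
#' @return List with `output` (m x d_v) and `weights` (m x n attention
#'   matrix; each row sums to 1 over unmasked positions).
#' @export
scaled_dot_product_attention <- function(Q, K, V, mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) abort("attention: Q and K must share d_k.")
  if (nrow(K) != nrow(V)) abort("attention: K and V must have equal row counts.")
  d_k <- ncol(Q)
  scores <- Q %*% t(K) / sqrt(d_k)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(scores))) abort("attention: mask must be m x n.")
    if (any(rowSums(mask) == 0)) {
      abort("attention: a query row has every key position masked out.")
    }
    scores[!mask] <- -Inf
  }
  w <- softmax_rows(scores)
  list(output = w %*% V, weights = w)
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Multi-head attention
#'
#' Splits the projected queries, keys and values into `n_heads` equal-width
#' blocks, runs [scaled_dot_product_attention()] per head, concatenates the
#' head outputs and projects once more: `Concat(head_1, ..., head_h) W_O`
#' with `head_i = Attention(Q W_Q[i], K W_K[i], V W_V[i])`.
#'
#' @param Q,K,V Input matrices (rows = positions, cols = d_model).
#' @param params List with full-width projection matrices `Wq`, `Wk`, `Wv`
#'   (d_model x n_heads*d_k) and `Wo` (n_heads*d_v x d_model); head `i` owns
#'   the i-th block of columns.
#' @param n_heads Number of heads; must divide the projection widths.
#' @param mask Optional logical mask as in [scaled_dot_product_attention()],
#'   shared across heads.
#' @return List with `output` (m x d_model) and `weights` (list of per-head
#'   attention matrices).
#' @export
multihead_attention <- function(Q, K, V, params, n_heads, mask = NULL) {
  Qp <- as.matrix(Q) %*% params$Wq
  Kp <- as.matrix(K) %*% params$Wk
  Vp <- as.matrix(V) %*% params$Wv
  if (ncol(Qp) %% n_heads != 0 || ncol(Vp) %% n_heads != 0) {
    abort("multihead_attention: projection width not divisible by n_heads.")
  }
  d_k <- ncol(Qp) %/% n_heads
  d_v <- ncol(Vp) %/% n_heads
  heads <- vector("list", n_heads)
  weights <- vector("list", n_heads)
  for (i in seq_len(n_heads)) {
    qc <- (i - 1) * d_k + seq_len(d_k)
    vc <- (i - 1) * d_v + seq_len(d_v)
    h <- scaled_dot_product_attention(Qp[, qc, drop = FALSE],
                                      Kp[, qc, drop = FALSE],
                                      Vp[, vc, drop = FALSE], mask)
    heads[[i]] <- h$output
    weights[[i]] <- h$weights
  }
  concat <- do.call(cbind, heads)
  if (nrow(params$Wo) != ncol(concat)) {
    abort("multihead_attention: Wo rows must equal n_heads * d_v.")
  }
  list(output = concat %*% params$Wo, weights = weights)
}

#' Sinusoidal positional encoding table
#'
#' Row `pos + 1` holds the encoding of position `pos` (positions start at 0):
#' `PE(pos, 2i) = sin(pos / base^(2i/d_model))` and
#' `PE(pos, 2i+1) = cos(pos / base^(2i/d_model))`. All entries lie in
#' \[-1, 1\]; position 0 is 0 at even dimensions and 1 at odd ones.
#'
#' @param max_len Number of positions (rows).
#' @param d_model Embedding width; must be even.
#' @param pe_base Denominator base. Default 10000 (the classic choice; some
#'   descriptions print 1000 — configurable for that reason).
#' @return `max_len` x `d_model` matrix of class `smi_pe`.
#' @export
positional_encoding <- function(max_len, d_model, pe_base = 10000) {
  stopifnot(max_len >= 1)
  if (d_model %% 2 != 0) abort("positional_encoding: d_model must be even.")
  pos <- 0:(max_len - 1)
  i <- 0:(d_model / 2 - 1)
  angle <- outer(pos, pe_base^(-2 * i / d_model))
  pe <- matrix(0, max_len, d_model)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  structure(pe, class = c("smi_pe", "matrix", "array"), pe_base = pe_base)
}

#' Layer normalization
#'
#' Normalizes each row to zero mean and unit variance, then applies the
#' learned gain and bias.
#'
#' @param x Input matrix (rows = positions).
#' @param g,b Gain and bias vectors of length `ncol(x)`.
#' @param eps Variance floor.
#' @return Matrix of the same shape.
#' @export
layer_norm <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  ((x - mu) / sqrt(v + eps)) %*% diag(g, ncol(x)) +
    matrix(b, nrow(x), ncol(x), byrow = TRUE)
}
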