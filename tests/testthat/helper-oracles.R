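# Independent oracles used across the suite. These deliberately re-derive
# results by the most transparent method available (plain DP, explicit loops,
# exhaustive enumeration) and never call the code paths they check.

# Affine-gap global alignment (Gotoh three-matrix DP); a gap of length L
# costs open + L * ext, end gaps penalized. When several alignments tie on
# the optimal score they can differ in identical-column count and alignment
# length, so alongside the exact score this oracle reports a guaranteed
# envelope for percent identity over ALL optimal alignments (independent
# extremes of identity count and column count among optimal paths); a
# correct implementation must land inside that interval.
oracle_global_alignment <- function(a, b, mat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  layer <- function() {
    list(s = matrix(NEG, n + 1, m + 1), idmax = matrix(0, n + 1, m + 1),
         idmin = matrix(0, n + 1, m + 1), clmax = matrix(0, n + 1, m + 1),
         clmin = matrix(0, n + 1, m + 1))
  }
  M <- layer(); X <- layer(); Y <- layer()
  M$s[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X$s[i, 1] <- -open - (i - 1) * ext
    X$clmax[i, 1] <- X$clmin[i, 1] <- i - 1
  }
  for (j in 2:(m + 1)) {
    Y$s[1, j] <- -open - (j - 1) * ext
    Y$clmax[1, j] <- Y$clmin[1, j] <- j - 1
  }
  # cands: rows of (score, idmax, idmin, clmax, clmin); keep score-optimal
  # rows and take independent extremes of the bookkeeping columns
  combine <- function(cands, add_score, add_ident, add_cols) {
    cm <- do.call(rbind, cands)
    top <- max(cm[, 1])
    sel <- cm[cm[, 1] >= top - 1e-9, , drop = FALSE]
    c(top + add_score, max(sel[, 2]) + add_ident, min(sel[, 3]) + add_ident,
      max(sel[, 4]) + add_cols, min(sel[, 5]) + add_cols)
  }
  at <- function(L, i, j, ds = 0) {
    c(L$s[i, j] + ds, L$idmax[i, j], L$idmin[i, j], L$clmax[i, j],
      L$clmin[i, j])
  }
  put <- function(L, i, j, v) {
    L$s[i, j] <- v[1]; L$idmax[i, j] <- v[2]; L$idmin[i, j] <- v[3]
    L$clmax[i, j] <- v[4]; L$clmin[i, j] <- v[5]
    L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      hit <- as.numeric(A[i - 1] == B[j - 1])
      M <- put(M, i, j, combine(list(at(M, i - 1, j - 1), at(X, i - 1, j - 1),
                                     at(Y, i - 1, j - 1)), s, hit, 1))
      X <- put(X, i, j, combine(list(at(M, i - 1, j, -open),
                                     at(X, i - 1, j),
                                     at(Y, i - 1, j, -open)), -ext, 0, 1))
      Y <- put(Y, i, j, combine(list(at(M, i, j - 1, -open),
                                     at(Y, i, j - 1),
                                     at(X, i, j - 1, -open)), -ext, 0, 1))
    }
  }
  fin <- combine(list(at(M, n + 1, m + 1), at(X, n + 1, m + 1),
                      at(Y, n + 1, m + 1)), 0, 0, 0)
  list(score = fin[1],
       identity_pct_max = 100 * fin[2] / max(fin[5], 1),
       identity_pct_min = 100 * fin[3] / max(fin[4], 1))
}

random_protein <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Per-row attention oracle: explicit softmax and weighted sum, one query row
# at a time.
oracle_attention <- function(Q, K, V, mask = NULL) {
  d_k <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- as.numeric(Q[i, ] %*% t(K)) / sqrt(d_k)
    if (!is.null(mask)) s[!mask[i, ]] <- -Inf
    w <- exp(s - max(s))
    w <- w / sum(w)
    out[i, ] <- colSums(w * V)
  }
  out
}

# A random tabulated autoregressive toy model: conditional log-prob tables
# keyed by the full prefix. Returns a step function compatible with
# beam_search() plus the tables for enumeration.
make_toy_lm <- function(vocab_size, seed) {
  force(vocab_size)
  tabs <- new.env(parent = emptyenv())
  key_seed <- function(key) {
    # per-prefix seed so the table is a pure function of (seed, prefix),
    # independent of the order in which prefixes are first visited
    h <- seed
    for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
    as.integer(h)
  }
  logp_for <- function(prefix_key) {
    if (is.null(tabs[[prefix_key]])) {
      p <- withr::with_seed(key_seed(prefix_key), stats::runif(vocab_size))
      p[1] <- 0  # PAD never proposed
      p[2] <- 0  # BOS never proposed
      p <- p / sum(p)
      tabs[[prefix_key]] <- log(p)
    }
    tabs[[prefix_key]]
  }
  step_fn <- function(prefixes) {
    t(apply(prefixes, 1, function(pre) logp_for(paste(pre, collapse = ","))))
  }
  list(step_fn = step_fn, logp_for = logp_for)
}

# Exhaustively enumerate and score every complete sequence of the toy model:
# content tokens from ids >= 3 plus EOS (id 2) at the end (EOS log-prob
# included); sequences may also end by hitting max_len, where EOS is forced.
oracle_enumerate <- function(toy, vocab_size, max_len, bos_id = 1L,
                             eos_id = 2L) {
  content <- setdiff(seq_len(vocab_size) - 1L, c(0L, bos_id))
  results <- list()
  recurse <- function(prefix, logp) {
    key <- paste(c(bos_id, prefix), collapse = ",")
    lp <- toy$logp_for(key)
    # stop here with EOS
    results[[length(results) + 1]] <<- list(ids = prefix,
                                            logprob = logp + lp[eos_id + 1])
    if (length(prefix) < max_len) {
      for (tok in setdiff(content, eos_id)) {
        recurse(c(prefix, tok), logp + lp[tok + 1])
      }
    }
  }
  recurse(integer(0), 0)
  ord <- order(-vapply(results, `[[`, numeric(1), "logprob"))
  results[ord]
}

# Shared tiny grammar fixtures (built once per test run)
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- smiformer::toy_grammar(seed = 42)
      cache <<- list(
        grammar = g,
        pairs = smiformer::make_toy_pairs(g, n_pairs = 48, protein_len = 40,
                                          seed = 101))
    }
    cache
  }
})

tiny_model_config <- function(...) {
  smiformer::model_config(n_layers = 1, d_model = 16, n_heads = 2, d_ff = 32,
                          dropout = 0, warmup_steps = 50, max_source_len = 60,
                          max_target_len = 40, ...)
}
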