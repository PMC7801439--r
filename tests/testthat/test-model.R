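test_that("model_config validates its invariants", {
  expect_error(model_config(d_model = 130, n_heads = 4), "divisible")
  expect_error(model_config(dropout = 1), "dropout")
  cfg <- model_config()
  expect_equal(cfg$n_layers, 4L)
  expect_equal(cfg$d_model, 128L)
  expect_equal(cfg$n_heads, 4L)
  expect_equal(cfg$d_ff, 512L)
})

test_that("a zero-layer encoder reduces to embedding plus positional encoding", {
  # classic sublayer-then-normalize composition: no final layer norm
  cfg <- model_config(n_layers = 0, d_model = 8, n_heads = 2, d_ff = 16,
                      dropout = 0, max_source_len = 20, max_target_len = 20,
                      norm_position = "post")
  w <- init_weights(cfg, vocab_size = 7, seed = 1)
  src <- c(3L, 4L, 5L)
  got <- encoder_forward(src, w, cfg)
  pe <- positional_encoding(3, 8, cfg$pe_base)
  want <- w$src_emb[src + 1L, ] * sqrt(8) + unclass(pe)[1:3, ]
  expect_equal(got, want)
})

test_that("decoder rows are probability distributions and decoding is causal", {
  withr::local_seed(6)
  cfg <- tiny_model_config()
  w <- init_weights(cfg, vocab_size = 9, seed = 2)
  src <- c(3L, 4L, 5L, 6L)
  ctx <- encoder_forward(src, w, cfg)
  for (k in 1:20) {
    prefix <- c(1L, sample(3:8, sample(1:6, 1), replace = TRUE))
    p <- decoder_forward(prefix, ctx, w, cfg)
    expect_equal(unname(rowSums(p)), rep(1, length(prefix)), tolerance = 1e-6)
    expect_true(all(p >= 0))
    # perturbing token t+1 leaves rows <= t unchanged
    t <- sample(seq_len(length(prefix) - 1), 1)
    pert <- prefix
    pert[t + 1] <- sample(setdiff(3:8, prefix[t + 1]), 1)
    p2 <- decoder_forward(pert, ctx, w, cfg)
    expect_equal(p[seq_len(t), , drop = FALSE], p2[seq_len(t), , drop = FALSE],
                 tolerance = 1e-12)
  }
})

test_that("identical batch members produce identical context rows", {
  cfg <- tiny_model_config()
  w <- init_weights(cfg, vocab_size = 9, seed = 3)
  src <- c(3L, 5L, 7L)
  expect_identical(encoder_forward(src, w, cfg), encoder_forward(src, w, cfg))
})

test_that("the compiled forward agrees with the reference R forward", {
  fx <- toy_fixture()
  vocab <- build_vocabulary(tibble::tibble(
    protein_sequence = fx$pairs$protein_sequence,
    canonical_smiles = fx$pairs$smiles))
  for (np in c("pre", "post")) {
    cfg <- model_config(n_layers = 2, d_model = 32, n_heads = 4, d_ff = 64,
                        dropout = 0, max_source_len = 60, max_target_len = 40,
                        norm_position = np)
    w <- init_weights(cfg, vocab$size, seed = 4)
    flat <- smiformer:::flatten_weights(w)
    ccfg <- smiformer:::cfg_for_cpp(cfg, vocab)
    src <- encode(fx$pairs$protein_sequence[1], vocab, "source")
    ctx_r <- encoder_forward(src, w, cfg)
    ctx_c <- smiformer:::cpp_encode(flat, ccfg, src)
    expect_equal(ctx_c, ctx_r, tolerance = 1e-10, info = np)
    prefix <- encode(fx$pairs$smiles[1], vocab, "target")[1:5]
    p_r <- decoder_forward(prefix, ctx_r, w, cfg)
    lp_c <- smiformer:::cpp_decode_logprobs(flat, ccfg, ctx_c,
                                            matrix(prefix, 1), src)
    expect_equal(lp_c[1, ], log(p_r[5, ]), tolerance = 1e-8, info = np)
  }
})

test_that("flatten/unflatten weight layout round-trips", {
  cfg <- tiny_model_config()
  w <- init_weights(cfg, vocab_size = 11, seed = 5)
  back <- smiformer:::unflatten_weights(smiformer:::flatten_weights(w), cfg)
  expect_equal(unclass(back), unclass(w), ignore_attr = TRUE)
})

test_that("compiled gradients match finite differences on a tiny model", {
  withr::local_seed(9)
  for (np in c("pre", "post")) {
    cfg <- model_config(n_layers = 2, d_model = 8, n_heads = 2, d_ff = 16,
                        dropout = 0, label_smoothing = 0.1,
                        max_source_len = 20, max_target_len = 20,
                        norm_position = np)
    vs <- 9L
    flat <- smiformer:::flatten_weights(init_weights(cfg, vs, seed = 5))
    ccfg <- c(unclass(cfg), list(vocab_size = vs))
    batch <- list(src = rbind(c(3L, 4L, 5L, 6L), c(4L, 4L, 3L, 0L)),
                  tgt_in = rbind(c(1L, 3L, 5L), c(1L, 6L, 0L)),
                  tgt_out = rbind(c(3L, 5L, 2L), c(6L, 2L, 0L)))
    lg <- smiformer:::cpp_loss_grads(flat, ccfg, batch)
    for (k in 1:25) {
      pi <- sample(length(flat), 1)
      el <- sample(length(flat[[pi]]), 1)
      eps <- 1e-6
      fp <- flat; fp[[pi]][el] <- fp[[pi]][el] + eps
      fm <- flat; fm[[pi]][el] <- fm[[pi]][el] - eps
      num <- (smiformer:::cpp_loss(fp, ccfg, batch) -
                smiformer:::cpp_loss(fm, ccfg, batch)) / (2 * eps)
      ana <- lg$grads[[pi]][el]
      expect_equal(ana, num, tolerance = 1e-4,
                   info = sprintf("%s param %s elem %d", np,
                                  names(flat)[pi], el))
    }
  }
})

test_that("the learning-rate schedule matches its closed form", {
  d <- 128; warmup <- 4000
  for (step in c(1, warmup, 10 * warmup)) {
    expect_equal(lr_schedule(step, d, warmup),
                 d^(-0.5) * min(step^(-0.5), step * warmup^(-1.5)))
  }
  # warmup phase is linear in step; decay phase is step^(-1/2)
  expect_equal(lr_schedule(2000, d, warmup) / lr_schedule(1000, d, warmup), 2)
  expect_equal(lr_schedule(40000, d, warmup) / lr_schedule(10000, d, warmup),
               0.5)
})

test_that("layer_norm normalizes rows and applies gain/bias", {
  x <- rbind(c(1, 2, 3, 4), c(-2, 0, 2, 4))
  g <- c(2, 2, 2, 2); b <- c(1, 1, 1, 1)
  y <- layer_norm(x, g, b)
  xh <- (y - 1) / 2
  expect_equal(rowMeans(xh), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(xh, 1, function(r) mean(r^2)), c(1, 1), tolerance = 1e-3)
})
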