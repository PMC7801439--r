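test_that("a short training run reduces the loss on toy pairs", {
  fx <- toy_fixture()
  cfg <- tiny_model_config()
  m <- train_model(fx$pairs[1:32, ], cfg, steps = 50, batch_tokens = 512,
                   seed = 7, log_every = 1)
  expect_lt(utils::tail(m$log$loss, 1), m$log$loss[1])
  expect_equal(m$step, 50L)
})

test_that("training is deterministic and resume matches an uninterrupted run", {
  fx <- toy_fixture()
  cfg <- tiny_model_config()
  full <- train_model(fx$pairs[1:24, ], cfg, steps = 40, batch_tokens = 256,
                      seed = 11, log_every = 5)
  again <- train_model(fx$pairs[1:24, ], cfg, steps = 40, batch_tokens = 256,
                       seed = 11, log_every = 5)
  expect_identical(full$weights, again$weights)

  part <- train_model(fx$pairs[1:24, ], cfg, steps = 20, batch_tokens = 256,
                      seed = 11, log_every = 5)
  resumed <- train_model(fx$pairs[1:24, ], steps = 20, batch_tokens = 256,
                         seed = 11, init = part, log_every = 5)
  expect_equal(resumed$step, 40L)
  expect_equal(resumed$weights, full$weights, tolerance = 1e-5)
  # logged loss trajectory of the resumed half matches the full run at the
  # steps both runs recorded
  common <- intersect(full$log$step, resumed$log$step)
  common <- common[common > 20]
  expect_equal(resumed$log$loss[match(common, resumed$log$step)],
               full$log$loss[match(common, full$log$step)], tolerance = 1e-4)
})

test_that("checkpoints round-trip and refuse a mismatched vocabulary", {
  fx <- toy_fixture()
  cfg <- tiny_model_config()
  m <- train_model(fx$pairs[1:16, ], cfg, steps = 10, batch_tokens = 256,
                   seed = 2, log_every = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_equal(back$weights, m$weights)

  other <- tibble::tibble(
    protein_sequence = c("MMMM", "KKKK"),
    smiles = c("N#N", "O=O"))  # different symbol set -> different vocabulary
  expect_error(train_model(other, steps = 5, init = back), "vocabulary")
})

test_that("tidy and glance expose the training log and model summary", {
  fx <- toy_fixture()
  cfg <- tiny_model_config()
  m <- train_model(fx$pairs[1:16, ], cfg, steps = 10, batch_tokens = 256,
                   seed = 2, log_every = 2)
  td <- generics::tidy(m)
  expect_true(all(c("step", "lr", "loss") %in% names(td)))
  expect_equal(td$lr, lr_schedule(td$step, cfg$d_model, cfg$warmup_steps),
               tolerance = 1e-12)
  gl <- generics::glance(m)
  expect_equal(gl$steps, 10L)
  expect_gt(gl$n_parameters, 1000)
})

test_that("token-count batching respects the budget and covers every pair", {
  fx <- toy_fixture()
  vocab <- build_vocabulary(tibble::tibble(
    protein_sequence = fx$pairs$protein_sequence,
    canonical_smiles = fx$pairs$smiles))
  batches <- smiformer:::make_batches(fx$pairs, vocab, batch_tokens = 512)
  n_seq <- sum(vapply(batches, function(b) nrow(b$src), numeric(1)))
  expect_equal(n_seq, nrow(fx$pairs))
  for (b in batches) {
    expect_equal(ncol(b$tgt_in), ncol(b$tgt_out))
    # teacher forcing alignment: tgt_out is tgt_in shifted by one
    expect_true(all(b$tgt_in[, 1] == 1L))  # BOS
  }
})
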