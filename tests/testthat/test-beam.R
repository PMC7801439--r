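test_that("a deterministic one-hot model forces its single sequence at log-prob ~0", {
  forced <- c(3L, 4L, 3L)
  step_fn <- function(prefixes) {
    t(apply(prefixes, 1, function(pre) {
      lp <- rep(-1e9, 5)
      pos <- length(pre)  # BOS + generated so far
      nxt <- if (pos <= length(forced)) forced[pos] else 2L
      lp[nxt + 1] <- 0
      lp
    }))
  }
  beam <- beam_search(step_fn, vocab_size = 5, beam_size = 3, max_len = 6)
  expect_equal(beam$ids[[1]], forced)
  expect_equal(beam$logprob[1], 0)
})

test_that("beam search with full width reproduces exhaustive enumeration", {
  for (seed in c(11, 23)) {
    toy <- make_toy_lm(vocab_size = 5, seed = seed)
    want <- oracle_enumerate(toy, vocab_size = 5, max_len = 3)
    beam <- beam_search(toy$step_fn, vocab_size = 5, beam_size = 5^3,
                        max_len = 3)
    expect_equal(nrow(beam), length(want))
    for (i in seq_along(want)) {
      expect_equal(beam$ids[[i]], want[[i]]$ids, info = sprintf("rank %d", i))
      expect_equal(beam$logprob[i], want[[i]]$logprob, tolerance = 1e-12)
    }
  }
})

test_that("beam size one equals greedy argmax decoding", {
  for (seed in 1:20) {
    toy <- make_toy_lm(vocab_size = 6, seed = 100 + seed)
    beam <- beam_search(toy$step_fn, vocab_size = 6, beam_size = 1,
                        max_len = 5)
    # manual greedy rollout
    prefix <- 1L
    repeat {
      lp <- toy$logp_for(paste(prefix, collapse = ","))
      lp[c(1, 2)] <- -Inf
      nxt <- which.max(lp) - 1L
      if (nxt == 2L || length(prefix) - 1L >= 5) break
      prefix <- c(prefix, nxt)
    }
    expect_equal(beam$ids[[1]], prefix[-1], info = sprintf("seed %d", seed))
  }
})

test_that("the best score is nondecreasing in beam size", {
  for (seed in c(5, 17, 31)) {
    toy <- make_toy_lm(vocab_size = 5, seed = seed)
    best <- vapply(c(1, 2, 4, 8, 125), function(bs) {
      beam_search(toy$step_fn, vocab_size = 5, beam_size = bs,
                  max_len = 3)$logprob[1]
    }, numeric(1))
    expect_true(all(diff(best) >= -1e-12))
  }
})

test_that("beam scores are nonincreasing down the ranking", {
  toy <- make_toy_lm(vocab_size = 5, seed = 77)
  beam <- beam_search(toy$step_fn, vocab_size = 5, beam_size = 10, max_len = 3)
  expect_true(all(diff(beam$logprob) <= 1e-12))
})

test_that("generated candidates re-score to their reported log-probs", {
  fx <- toy_fixture()
  cfg <- tiny_model_config()
  m <- train_model(fx$pairs, cfg, steps = 30, batch_tokens = 512, seed = 3,
                   log_every = 10)
  prot <- fx$pairs$protein_sequence[1]
  res <- generate(m, prot, mode = "ten_per_one")
  expect_lte(nrow(res), 10)
  expect_true(all(diff(res$logprob) <= 1e-9))
  enc <- smiformer:::encode_protein(m, prot)
  step_fn <- smiformer:::model_step_fn(m, enc$src_ids, enc$memory)
  for (i in seq_len(min(3, nrow(res)))) {
    ids <- encode(res$smiles[i], m$vocab, kind = "target")
    lp <- 0
    for (t in 2:length(ids)) {
      row <- step_fn(matrix(ids[seq_len(t - 1)], 1))
      lp <- lp + row[1, ids[t] + 1]
    }
    expect_equal(lp, res$logprob[i], tolerance = 1e-5)
  }
})

test_that("generation modes honor their candidate-count contracts", {
  fx <- toy_fixture()
  cfg <- tiny_model_config()
  m <- train_model(fx$pairs, cfg, steps = 30, batch_tokens = 512, seed = 4,
                   log_every = 10)
  prot <- fx$pairs$protein_sequence[2]
  one <- generate(m, prot, mode = "one_per_one")
  expect_equal(nrow(one), 1)
  ten <- generate(m, prot, mode = "ten_per_one")
  expect_lte(nrow(ten), 10)
  expect_false(any(duplicated(ten$smiles)))
  # the wider beam can only improve the top hypothesis
  expect_gte(ten$logprob[1], one$logprob[1] - 1e-9)
  expect_error(beam_search(function(p) matrix(0, 1, 5), 5, beam_size = 0),
               "beam_size")
})
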