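test_that("attention of a single query/key returns the value row unchanged", {
  out <- scaled_dot_product_attention(matrix(2), matrix(5), matrix(7))
  expect_equal(out$output, matrix(7))
  expect_equal(out$weights, matrix(1))
})

test_that("two identical keys average their values", {
  Q <- matrix(c(1, 0), 1, 2)
  K <- rbind(c(3, 1), c(3, 1))
  V <- rbind(c(10, 0), c(0, 4))
  out <- scaled_dot_product_attention(Q, K, V)
  expect_equal(out$output, matrix(c(5, 2), 1, 2))
})

test_that("attention matches the per-row softmax oracle on random instances", {
  withr::local_seed(1)
  for (k in 1:100) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    dk <- sample(1:4, 1); dv <- sample(1:4, 1)
    Q <- matrix(rnorm(m * dk), m)
    K <- matrix(rnorm(n * dk), n)
    V <- matrix(rnorm(n * dv), n)
    mask <- matrix(stats::runif(m * n) > 0.2, m, n)
    mask[rowSums(mask) == 0, 1] <- TRUE  # keep every row attendable
    got <- scaled_dot_product_attention(Q, K, V, mask)
    expect_equal(got$output, oracle_attention(Q, K, V, mask),
                 tolerance = 1e-6)
    expect_equal(unname(rowSums(got$weights)), rep(1, m), tolerance = 1e-12)
  }
})

test_that("attention outputs are convex combinations of value rows", {
  withr::local_seed(2)
  Q <- matrix(rnorm(12), 4)
  K <- matrix(rnorm(15), 5)
  V <- matrix(rnorm(10), 5)
  out <- scaled_dot_product_attention(Q, K, V)$output
  for (j in seq_len(ncol(V))) {
    expect_true(all(out[, j] >= min(V[, j]) - 1e-12))
    expect_true(all(out[, j] <= max(V[, j]) + 1e-12))
  }
})

test_that("attention rejects malformed inputs and fully masked rows", {
  expect_error(scaled_dot_product_attention(matrix(1, 2, 3), matrix(1, 2, 2),
                                            matrix(1, 2, 2)), "d_k")
  expect_error(scaled_dot_product_attention(matrix(1), matrix(1), matrix(1),
                                            mask = matrix(FALSE)), "masked")
})

test_that("multihead with identity projections equals single-head attention", {
  withr::local_seed(3)
  d <- 4
  Q <- matrix(rnorm(3 * d), 3)
  K <- matrix(rnorm(5 * d), 5)
  V <- matrix(rnorm(5 * d), 5)
  params <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d))
  mh <- multihead_attention(Q, K, V, params, n_heads = 1)
  sh <- scaled_dot_product_attention(Q, K, V)
  expect_equal(mh$output, sh$output)
})

test_that("multihead equals an oracle computing heads independently", {
  withr::local_seed(4)
  d <- 6; h <- 2; dh <- d / h
  Q <- matrix(rnorm(4 * d), 4)
  K <- matrix(rnorm(5 * d), 5)
  V <- matrix(rnorm(5 * d), 5)
  params <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
                 Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d))
  got <- multihead_attention(Q, K, V, params, n_heads = h)$output
  heads <- lapply(seq_len(h), function(i) {
    cols <- (i - 1) * dh + seq_len(dh)
    oracle_attention((Q %*% params$Wq)[, cols, drop = FALSE],
                     (K %*% params$Wk)[, cols, drop = FALSE],
                     (V %*% params$Wv)[, cols, drop = FALSE])
  })
  expect_equal(got, do.call(cbind, heads) %*% params$Wo, tolerance = 1e-10)
})

test_that("zero output projection kills the multihead output", {
  withr::local_seed(5)
  d <- 4
  X <- matrix(rnorm(3 * d), 3)
  params <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d),
                 Wo = matrix(0, d, d))
  expect_equal(multihead_attention(X, X, X, params, n_heads = 2)$output,
               matrix(0, 3, d))
})

test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(8, 6, pe_base = 10000)
  expect_equal(pe[1, ], rep(c(0, 1), 3))                 # position 0
  expect_equal(pe[4, 1], sin(3), tolerance = 1e-12)      # pos 3, dim 2i = 0
  expect_equal(pe[4, 1], 0.14112, tolerance = 1e-4)
  expect_equal(pe[4, 2], cos(3), tolerance = 1e-12)
  i <- 2  # dimension pair index
  expect_equal(pe[5, 2 * i + 1], sin(4 / 10000^(2 * i / 6)), tolerance = 1e-12)
  expect_true(all(pe >= -1 & pe <= 1))
  # the printed base 1000 variant is also supported via pe_base
  pe1k <- positional_encoding(8, 6, pe_base = 1000)
  expect_equal(pe1k[4, 3], sin(3 / 1000^(2 / 6)), tolerance = 1e-12)
  expect_error(positional_encoding(4, 5), "even")
})
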