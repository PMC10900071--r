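test_that("flatten uses last-axis-fastest raster order and round-trips", {
  arr <- array(0:7, c(2, 2, 2))
  storage.mode(arr) <- "integer"
  # place values so that raster order (axis 3 fastest) reads 0..7
  arr[1, 1, 1] <- 0L; arr[1, 1, 2] <- 1L; arr[1, 2, 1] <- 2L; arr[1, 2, 2] <- 3L
  arr[2, 1, 1] <- 4L; arr[2, 1, 2] <- 5L; arr[2, 2, 1] <- 6L; arr[2, 2, 2] <- 7L
  ts <- flatten_codes(arr, vocab = 8L)
  expect_equal(ts$tokens, 0:7)
  expect_identical(unflatten_codes(ts)$indices, arr)
  # random round trips
  set.seed(5)
  for (i in 1:5) {
    g <- array(sample(0:15, 3 * 4 * 5, replace = TRUE), c(3, 4, 5))
    expect_identical(unflatten_codes(flatten_codes(g, 16L))$indices, g)
  }
  # flattening is orientation-sensitive unless the grid is mirror-symmetric
  g <- array(sample(0:7, 8), c(2, 2, 2))
  gf <- g[2:1, , ]
  expect_false(identical(flatten_codes(g, 8L)$tokens,
                         flatten_codes(gf, 8L)$tokens))
  gs <- array(1L, c(2, 2, 2)) # mirror-symmetric
  expect_identical(flatten_codes(gs, 8L)$tokens, flatten_codes(gs[2:1, , ], 8L)$tokens)
})

test_that("a uniform model gives the closed-form log-likelihood", {
  cfg <- ar_config(n_layers = 1L, n_heads = 1L, d_model = 8L, mlp_mult = 2L,
                   seed = 1L)
  set.seed(1)
  params <- ltmood:::ar_init_params(cfg, 4L, 3L)
  params$Wout[] <- 0 # zero head: logits identical => uniform conditionals
  params$bout[] <- 0
  m <- make_ar_model(params, cfg, 4L, 3L)
  ll <- sequence_loglik(make_token_seq(c(2L, 0L, 3L), 4L), m)
  expect_equal(ll$total_loglik, 3 * log(1 / 4), tolerance = 1e-10)
  expect_equal(ll$per_token_logp, rep(log(0.25), 3), tolerance = 1e-10)
  # a model certain of the next token gives log-likelihood 0
  params$bout <- c(1000, 0, 0, 0)
  m1 <- make_ar_model(params, cfg, 4L, 3L)
  ll0 <- sequence_loglik(make_token_seq(c(0L, 0L, 0L), 4L), m1)
  expect_equal(ll0$total_loglik, 0, tolerance = 1e-8)
})

test_that("conditionals are normalised and the total is additive", {
  cfg <- ar_config(n_layers = 2L, n_heads = 2L, d_model = 16L, mlp_mult = 2L,
                   seed = 3L)
  set.seed(3)
  params <- ltmood:::ar_init_params(cfg, 6L, 10L)
  m <- make_ar_model(params, cfg, 6L, 10L)
  ts <- make_token_seq(sample(0:5, 10, replace = TRUE), 6L)
  C <- ar_conditionals(m, ts)
  expect_equal(rowSums(C), rep(1, 10), tolerance = 1e-5)
  expect_true(all(C >= 0))
  ll <- sequence_loglik(ts, m)
  expect_equal(ll$total_loglik, sum(ll$per_token_logp), tolerance = 1e-5)
  expect_true(all(ll$per_token_logp <= 0))
  expect_error(sequence_loglik(make_token_seq(c(0L, 6L, rep(0L, 8)), 6L), m),
               "vocabulary")
  expect_error(sequence_loglik(make_token_seq(rep(0L, 4), 6L), m), "length")
})

test_that("batched likelihood equals prefix-by-prefix evaluation", {
  cfg <- ar_config(n_layers = 2L, n_heads = 2L, d_model = 16L, mlp_mult = 2L,
                   seed = 4L)
  set.seed(4)
  Tn <- 12L; vocab <- 5L
  params <- ltmood:::ar_init_params(cfg, vocab, Tn)
  m <- make_ar_model(params, cfg, vocab, Tn)
  for (rep in 1:10) {
    tk <- sample(0:(vocab - 1L), Tn, replace = TRUE)
    ll <- sequence_loglik(make_token_seq(tk, vocab), m)
    # oracle: the conditional at position i may depend only on tokens < i, so
    # recompute each conditional with the suffix replaced by arbitrary tokens
    oracle <- vapply(seq_len(Tn), function(i) {
      junk <- tk
      if (i <= Tn) junk[i:Tn] <- sample(0:(vocab - 1L), Tn - i + 1L, replace = TRUE)
      C <- ar_conditionals(m, make_token_seq(junk, vocab))
      log(C[i, tk[i] + 1L])
    }, numeric(1))
    expect_equal(ll$per_token_logp, oracle, tolerance = 1e-9)
  }
})

test_that("training is seeded-deterministic and fits constant sequences", {
  seqs <- lapply(1:20, function(i) make_token_seq(rep(2L, 8L), 4L))
  cfg <- ar_config(n_layers = 1L, n_heads = 2L, d_model = 16L, mlp_mult = 2L,
                   epochs = 25L, batch_size = 8L, lr = 5e-3, seed = 11L)
  m1 <- train_ar(seqs, cfg)
  m2 <- train_ar(seqs, cfg)
  expect_identical(m1$curve, m2$curve)
  ll <- sequence_loglik(seqs[[1]], m1)
  expect_gt(ll$total_loglik / 8, -0.05) # per-token logp approaches 0
  # inconsistent inputs are rejected
  bad <- c(seqs, list(make_token_seq(rep(1L, 9L), 4L)))
  expect_error(train_ar(bad, cfg), "share")
})

test_that("spatial maps invert the raster order and upsample by nearest", {
  lr <- structure(list(total_loglik = -8 * 0.5, per_token_logp = rep(-0.5, 8),
                       latent_shape = c(2L, 2L, 2L)),
                  class = "likelihood_result")
  mp <- spatial_likelihood_map(lr, 3L)
  expect_equal(dim(mp), c(6L, 6L, 6L))
  expect_true(all(mp == -0.5))
  # shape arithmetic at full scale: latent (11,13,11) x 16
  lr2 <- structure(list(total_loglik = 0,
                        per_token_logp = rnorm(11 * 13 * 11),
                        latent_shape = c(11L, 13L, 11L)),
                   class = "likelihood_result")
  expect_equal(dim(spatial_likelihood_map(lr2, 16L)), c(176L, 208L, 176L))
  # exhaustive nearest-neighbour oracle on a 2x2x2 grid, factor 2
  vals <- rnorm(8)
  lr3 <- structure(list(total_loglik = sum(vals), per_token_logp = vals,
                        latent_shape = c(2L, 2L, 2L)),
                   class = "likelihood_result")
  mp3 <- spatial_likelihood_map(lr3, 2L)
  grid <- ltmood:::raster_unflatten(vals, c(2L, 2L, 2L))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_equal(mp3[i, j, k],
                 grid[ceiling(i / 2), ceiling(j / 2), ceiling(k / 2)])
  }
  expect_error(spatial_likelihood_map(lr, 0L), "factor")
})
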