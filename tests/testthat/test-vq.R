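test_that("latent shape arithmetic matches the stride-2 compression", {
  ls <- latent_shape(c(176L, 208L, 176L), 4L)
  expect_equal(ls$latent_shape, c(11L, 13L, 11L))
  expect_equal(ls$sequence_length, 1573L)
  expect_equal(latent_shape(c(28L, 28L), 2L)$latent_shape, c(7L, 7L))
  ls0 <- latent_shape(c(16L, 16L, 16L), 0L)
  expect_equal(ls0$latent_shape, c(16L, 16L, 16L))
  expect_equal(ls0$sequence_length, 4096L)
  # non-divisible dimensions are padded up to the next multiple
  lsp <- latent_shape(c(30L, 33L, 10L), 2L)
  expect_equal(lsp$padded_shape, c(32L, 36L, 12L))
  expect_equal(lsp$latent_shape, c(8L, 9L, 3L))
})

test_that("quantisation picks the L2-nearest entry with low-index ties", {
  cb <- new_codebook(8L, 4L, seed = 1L)
  # a vector equal to entry 4 (index 3, 0-based) maps to index 3
  expect_equal(vq_quantize(matrix(cb$entries[4, ], 1), cb), 3L)
  # K = 1 degenerate codebook: everything maps to index 0
  cb1 <- structure(list(entries = matrix(rnorm(4), 1), K = 1L, n = 4L),
                   class = "codebook")
  expect_true(all(vq_quantize(matrix(rnorm(40), 10), cb1) == 0L))
  # exact ties break to the lowest index
  cbt <- structure(list(entries = rbind(c(1, 0), c(1, 0)), K = 2L, n = 2L),
                   class = "codebook")
  expect_equal(vq_quantize(matrix(c(5, 5), 1), cbt), 0L)
  expect_error(vq_quantize(matrix(rnorm(6), 2), cb), "dimension")
})

test_that("quantisation agrees with exhaustive nearest-neighbour search", {
  set.seed(11)
  cb <- new_codebook(8L, 5L, seed = 2L)
  z <- matrix(rnorm(100 * 5), 100)
  got <- vq_quantize(z, cb)
  oracle <- apply(z, 1, function(v) {
    which.min(colSums((t(cb$entries) - v)^2)) - 1L
  })
  expect_equal(got, oracle)
  # and on a grid-shaped input
  zg <- array(rnorm(4 * 3 * 2 * 5), c(4, 3, 2, 5))
  gg <- vq_quantize(zg, cb)
  expect_equal(dim(gg), c(4L, 3L, 2L))
  expect_equal(as.vector(gg), apply(matrix(zg, ncol = 5), 1, function(v) {
    which.min(colSums((t(cb$entries) - v)^2)) - 1L
  }))
})

test_that("EMA updates recover cluster means and leave empty codes alone", {
  cb <- new_codebook(3L, 2L, seed = 3L)
  z <- rbind(c(0, 0), c(0.2, 0), c(10, 10), c(10.2, 10))
  asg <- c(0L, 0L, 1L, 1L)
  # decay 0: entries become exact batch cluster means for occupied codes
  cb0 <- vq_ema_update(cb, z, asg, decay = 0, eps = 1e-12)
  expect_equal(cb0$entries[1, ], c(0.1, 0), tolerance = 1e-6)
  expect_equal(cb0$entries[2, ], c(10.1, 10), tolerance = 1e-6)
  # an unassigned code is unchanged under decay > 0
  cb9 <- vq_ema_update(cb, z, asg, decay = 0.9)
  expect_equal(cb9$entries[3, ], cb$entries[3, ], tolerance = 1e-4)
  # repeated updates on a fixed batch converge geometrically to the means
  cbc <- cb
  for (i in 1:1000) cbc <- vq_ema_update(cbc, z, asg, decay = 0.99)
  expect_equal(cbc$entries[1, ], c(0.1, 0), tolerance = 1e-3)
  expect_equal(cbc$entries[2, ], c(10.1, 10), tolerance = 1e-3)
})

test_that("encode/decode preserve spatial shape, padded or not", {
  cfg <- vq_config(seed = 21L)
  m <- untrained_vq(c(32L, 32L, 32L), cfg)
  v <- generate_phantom(phantom_spec(seed = 1L))
  cg <- vq_encode(v, m)
  expect_equal(dim(cg$indices), c(8L, 8L, 8L))
  expect_true(all(cg$indices >= 0L & cg$indices < cfg$K))
  rec <- vq_decode(cg, m)
  expect_equal(dim(rec$intensities), c(32L, 32L, 32L))
  expect_true(all(is.finite(rec$intensities)))
  # a non-divisible shape goes through padding and comes back cropped
  m2 <- untrained_vq(c(10L, 14L, 9L), vq_config(seed = 4L))
  x <- array(runif(10 * 14 * 9), c(10, 14, 9))
  rec2 <- vq_decode(vq_encode(x, m2), m2)
  expect_equal(dim(rec2$intensities), c(10L, 14L, 9L))
  expect_true(all(is.finite(rec2$intensities)))
  expect_error(vq_encode(array(0, c(8, 8, 8)), m), "shape")
})

test_that("loss decomposition is exact and closed forms hold", {
  cfg <- vq_config(seed = 1L)
  x <- generate_phantom(phantom_spec(seed = 2L))$intensities
  # perfect reconstruction: mse and spectral are both 0
  l0 <- vq_loss(x, x, NULL, NULL, new_codebook(4L, 8L), cfg)
  expect_equal(l0$mse, 0)
  expect_equal(l0$spectral, 0, tolerance = 1e-12)
  # constant offset delta: mse = delta^2
  delta <- 0.13
  l1 <- vq_loss(x, x + delta, NULL, NULL, new_codebook(4L, 8L), cfg)
  expect_equal(l1$mse, delta^2, tolerance = 1e-10)
  expect_equal(l1$spectral, l1$mse, tolerance = 1e-8) # Parseval identity
  # with only the mse weight on, total == mse
  expect_equal(l1$total, l1$mse, tolerance = 1e-12)
  # full decomposition equals the weighted sum
  cfg2 <- vq_config(loss_weights = c(mse = 1, spectral = 0.5, perceptual = 0.3),
                    perceptual_extractor = random_conv_extractor(2L, seed = 5L),
                    seed = 1L)
  cb <- new_codebook(4L, 8L)
  z <- array(rnorm(4 * 4 * 4 * 8), c(4, 4, 4, 8))
  idx <- vq_quantize(z, cb)
  l2 <- vq_loss(x, x + delta, z, idx, cb, cfg2)
  expect_equal(l2$total,
               1 * l2$mse + 0.5 * l2$spectral + 0.3 * l2$perceptual +
                 l2$commitment,
               tolerance = 1e-6)
  expect_gt(l2$commitment, 0)
})

test_that("reconstruction MSE score and its normalised variant", {
  m <- untrained_vq(c(16L, 16L, 16L), vq_config(seed = 9L))
  v <- generate_phantom(small_spec(seed = 3L))
  sc <- reconstruction_mse(v, m)
  expect_equal(sc$normalised, sc$mse / mean(v$intensities))
  expect_true(sc$normalised_defined)
  zero <- array(0, c(16, 16, 16))
  expect_warning(sc0 <- reconstruction_mse(zero, m), "undefined")
  expect_false(sc0$normalised_defined)
  expect_true(is.na(sc0$normalised))
})

test_that("a trained VQ beats the dataset-mean predictor and uses its codes", {
  ex <- scaled_experiment()
  m <- ex$vq_model
  cohort <- generate_cohort(ex$phantom, 20L, base_seed = derive_seed(ex$seed, 1L))
  mean_img <- Reduce(`+`, lapply(cohort, function(v) v$intensities)) / 20
  rec_mse <- mean(vapply(cohort, function(v) reconstruction_mse(v, m)$mse,
                         numeric(1)))
  base_mse <- mean(vapply(cohort, function(v) mean((v$intensities - mean_img)^2),
                          numeric(1)))
  expect_lt(rec_mse, base_mse)
  codes <- unique(unlist(lapply(cohort, function(v)
    as.vector(vq_encode(v, m)$indices))))
  expect_gte(length(codes), 2L) # no codebook collapse
})

test_that("VQ training is deterministic given the seed", {
  cohort <- generate_cohort(small_spec(), 8L, base_seed = 31L)
  m2 <- train_vq(cohort, vq_config(epochs = 2L, seed = 6L))
  m3 <- train_vq(cohort, vq_config(epochs = 2L, seed = 6L))
  expect_identical(m2$curve, m3$curve)
  expect_identical(m2$codebook$entries, m3$codebook$entries)
})
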