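test_that("the default suite enumerates the fourteen corruption classes", {
  suite <- default_corruption_suite()
  expect_length(suite, 14L)
  labs <- names(suite)
  expect_true(all(c("noise_sd0.2", "bg_value1", "bg_value0.3", "bg_value0.6",
                    "flip_sagittal", "flip_coronal", "flip_axial",
                    "chunk_central", "chunk_upper", "skull_strip",
                    "scale_0.1", "scale_0.01") %in% labs))
  sds <- vapply(suite[grep("^noise", labs)], function(s) s$params$sd,
                numeric(1))
  expect_setequal(sds, c(0.01, 0.1, 0.2))
})

test_that("intensity scaling is multiplicative and scales the maximum", {
  v <- generate_phantom(small_spec(seed = 2L))
  v$intensities[2, 2, 2] <- 1 # pin the max at exactly 1
  out <- apply_corruption(v, corruption_spec("intensity_scale", factor = 0.1))
  expect_equal(max(out$volume$intensities), 0.1)
  # c1 then c2 equals c1*c2
  s1 <- apply_corruption(v, corruption_spec("intensity_scale", factor = 0.5))
  s2 <- apply_corruption(s1$volume, corruption_spec("intensity_scale", factor = 0.2))
  s12 <- apply_corruption(v, corruption_spec("intensity_scale", factor = 0.1))
  expect_equal(s2$volume$intensities, s12$volume$intensities, tolerance = 1e-6)
})

test_that("flips are involutions on intensities and masks, and commute", {
  v <- generate_phantom(small_spec(seed = 4L))
  for (plane in c("sagittal", "coronal", "axial")) {
    spec <- corruption_spec("flip", plane = plane)
    once <- apply_corruption(v, spec)$volume
    twice <- apply_corruption(once, spec)$volume
    expect_identical(twice$intensities, v$intensities)
    expect_identical(twice$lesion_mask, v$lesion_mask)
    expect_identical(twice$brain_mask, v$brain_mask)
  }
  ab <- apply_corruption(apply_corruption(v, corruption_spec("flip", plane = "sagittal"))$volume,
                         corruption_spec("flip", plane = "axial"))$volume
  ba <- apply_corruption(apply_corruption(v, corruption_spec("flip", plane = "axial"))$volume,
                         corruption_spec("flip", plane = "sagittal"))$volume
  expect_identical(ab$intensities, ba$intensities)
})

test_that("sagittal flip mirrors the lesion mask voxel-by-voxel", {
  v <- generate_phantom(small_spec(seed = 9L))
  out <- apply_corruption(v, corruption_spec("flip", plane = "sagittal"))$volume
  # brute-force voxelwise mirror oracle
  d <- dim(v$lesion_mask)
  oracle <- array(FALSE, d)
  for (i in seq_len(d[1])) oracle[i, , ] <- v$lesion_mask[d[1] - i + 1L, , ]
  expect_identical(out$lesion_mask, oracle)
  # centroid mirrors accordingly
  cm <- colMeans(which(v$lesion_mask, arr.ind = TRUE))
  cm_f <- colMeans(which(out$lesion_mask, arr.ind = TRUE))
  expect_equal(unname(cm_f[1]), d[1] + 1 - unname(cm[1]), tolerance = 1e-10)
})

test_that("background substitution changes exactly the zero voxels", {
  v <- generate_phantom(small_spec(seed = 5L))
  was_zero <- v$intensities == 0
  out <- apply_corruption(v, corruption_spec("background_value", value = 0.3))$volume
  expect_false(any(out$intensities == 0))
  expect_true(all(out$intensities[was_zero] == 0.3))
  expect_identical(out$intensities[!was_zero], v$intensities[!was_zero])
})

test_that("noise is seeded, unclamped, and sd 0 is the identity", {
  v <- generate_phantom(small_spec(seed = 6L))
  id <- apply_corruption(v, corruption_spec("noise", sd = 0))$volume
  expect_equal(id$intensities, v$intensities)
  n1 <- apply_corruption(v, corruption_spec("noise", sd = 0.2, seed = 3L))$volume
  n2 <- apply_corruption(v, corruption_spec("noise", sd = 0.2, seed = 3L))$volume
  expect_identical(n1$intensities, n2$intensities)
  expect_gt(max(n1$intensities), 1) # no clamping of the noise
  expect_lt(min(n1$intensities), 0)
})

test_that("chunk deletion zeroes a block of floor(f * extent) axial slices", {
  v <- generate_phantom(small_spec(seed = 8L))
  nz <- dim(v$intensities)[3]
  out <- apply_corruption(v, corruption_spec("chunk_delete", location = "central",
                                             fraction = 0.25))$volume
  sl <- chunk_slice_range(nz, "central", 0.25)
  expect_length(sl, floor(0.25 * nz))
  expect_true(all(out$intensities[, , sl] == 0))
  keep <- setdiff(seq_len(nz), sl)
  expect_identical(out$intensities[, , keep], v$intensities[, , keep])
  up <- apply_corruption(v, corruption_spec("chunk_delete", location = "upper"))$volume
  expect_true(all(up$intensities[, , chunk_slice_range(nz, "upper", 0.2)] == 0))
})

test_that("skull stripping zeroes outside the brain and needs a mask", {
  v <- generate_phantom(small_spec(seed = 2L))
  out <- apply_corruption(v, corruption_spec("skull_strip"))$volume
  expect_true(all(out$intensities[!v$brain_mask] == 0))
  expect_identical(out$intensities[v$brain_mask], v$intensities[v$brain_mask])
  v2 <- v; v2$brain_mask <- NULL
  expect_error(apply_corruption(v2, corruption_spec("skull_strip")), "brain_mask")
})

test_that("cohort corruption yields |cohort| x |suite| tagged outputs", {
  cohort <- generate_cohort(small_spec(), 47L, base_seed = 10L)
  suite <- default_corruption_suite()
  out <- corrupt_cohort(cohort, suite)
  expect_length(out, 47L * 14L)
  man <- corruption_manifest(out)
  expect_equal(nrow(man), 658L)
  expect_true(all(man$is_ood == 1L))
  expect_equal(sum(man$corruption_label == "scale_0.1"), 47L)
  one <- corrupt_cohort(cohort[1], suite[1])
  expect_length(one, 1L)
  expect_error(corrupt_cohort(cohort, list()), "non-empty")
  expect_error(corrupt_cohort(list(), suite), "non-empty")
})

test_that("cohort corruption can skip failing combinations with a warning", {
  v <- generate_phantom(small_spec(seed = 1L))
  v$brain_mask <- NULL
  suite <- default_corruption_suite()
  expect_error(corrupt_cohort(list(v), suite), "brain_mask")
  expect_warning(out <- corrupt_cohort(list(v), suite, on_error = "skip"),
                 "skipping skull_strip")
  expect_length(out, 13L)
})
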