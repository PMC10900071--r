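test_that("voxel certainty matches binary-entropy closed forms", {
  a <- array(1, c(2, 2, 2))
  cert <- voxel_certainty(rep(list(a), 5), "ensemble_entropy")
  expect_true(all(cert$values == 1)) # full agreement => H = 0 => certainty 1
  half <- array(0.5, c(2, 2, 2))
  c2 <- voxel_certainty(list(half), "ensemble_entropy")
  expect_equal(c2$values[1, 1, 1], 1 - log(2), tolerance = 1e-12)
  # softmax baseline is the foreground probability itself
  p <- array(runif(8), c(2, 2, 2))
  expect_equal(voxel_certainty(list(p), "softmax")$values, p)
  expect_error(voxel_certainty(list(array(1.5, c(2, 2, 2)))), "\\[0, 1\\]")
})

test_that("certainty equals a scalar-loop entropy oracle voxel by voxel", {
  set.seed(21)
  stack <- lapply(1:5, function(i) array(runif(4 * 3 * 2), c(4, 3, 2)))
  cert <- voxel_certainty(stack, "ensemble_entropy")
  for (i in 1:4) for (j in 1:3) for (k in 1:2) {
    pbar <- mean(vapply(stack, function(s) s[i, j, k], numeric(1)))
    H <- 0
    for (pc in c(pbar, 1 - pbar)) if (pc > 0) H <- H - pc * log(pc)
    expect_equal(cert$values[i, j, k], 1 - H, tolerance = 1e-12)
  }
  # permutation invariance in the ensemble members
  cert_perm <- voxel_certainty(stack[c(3, 1, 5, 2, 4)], "ensemble_entropy")
  expect_equal(cert$values, cert_perm$values)
  # certainty is 1 only where all members agree with probability 0 or 1
  stack2 <- list(array(c(1, 0, 0.6, 1), c(2, 2, 1)),
                 array(c(1, 0, 0.6, 0.8), c(2, 2, 1)))
  cv <- voxel_certainty(stack2, "ensemble_entropy")$values
  expect_equal(cv[1, 1, 1], 1)
  expect_equal(cv[2, 1, 1], 1)
  expect_lt(cv[1, 2, 1], 1)
  expect_lt(cv[2, 2, 1], 1)
})

test_that("majority vote and lesion scoring aggregate per component", {
  d <- c(8L, 8L, 4L)
  mk <- function(val) array(val, d)
  # two disjoint blobs with constant certainties 0.2 and 0.8
  pred <- array(0, d)
  pred[2:3, 2:3, 2] <- 1
  pred[6:7, 6:7, 3] <- 1
  stack <- rep(list(pred), 5)
  cert <- structure(list(values = mk(0), method = "ensemble_entropy"),
                    class = "certainty_map")
  cert$values[2:3, 2:3, 2] <- 0.2
  cert$values[6:7, 6:7, 3] <- 0.8
  sc <- lesion_scores(cert, stack)
  expect_equal(nrow(sc), 2L)
  expect_setequal(round(sc$confidence, 10), c(0.2, 0.8))
  expect_true(all(sc$n_voxels == 4L))
  # per-voxel averaging oracle
  for (r in seq_len(nrow(sc))) {
    expect_equal(sc$confidence[r], mean(cert$values[sc$voxels[[r]]]))
    expect_gte(sc$confidence[r], min(cert$values[sc$voxels[[r]]]))
    expect_lte(sc$confidence[r], max(cert$values[sc$voxels[[r]]]))
  }
  # majority vote: 3 of 5 positive => positive
  stack35 <- c(rep(list(mk(1)), 3), rep(list(mk(0)), 2))
  expect_true(all(majority_vote(stack35)))
  stack25 <- c(rep(list(mk(1)), 2), rep(list(mk(0)), 3))
  expect_false(any(majority_vote(stack25)))
  # empty prediction gives an empty table, not an error
  sc0 <- lesion_scores(cert, rep(list(mk(0)), 5))
  expect_equal(nrow(sc0), 0L)
})

test_that("connected components respect the declared connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE # diagonal neighbour: connected under 26, not under 6
  m[4, 4, 4] <- TRUE
  c26 <- connected_components_3d(m, 26L)
  expect_length(c26, 2L)
  c6 <- connected_components_3d(m, 6L)
  expect_length(c6, 3L)
  expect_setequal(unlist(c26), which(m))
  expect_length(connected_components_3d(array(FALSE, c(3, 3, 3))), 0L)
})

test_that("TP/FP labelling uses the 50% predicted-overlap rule", {
  d <- c(8L, 8L, 2L)
  gt <- array(FALSE, d); gt[1:4, 1:4, 1] <- TRUE
  mkscore <- function(vox) tibble::tibble(
    component_id = 1L, n_voxels = length(vox), confidence = 0.5,
    is_tp = NA, voxels = list(vox))
  inside <- which(array(seq_len(prod(d)), d) %in% which(gt))[1:4]
  expect_true(label_tp_fp(mkscore(which(gt)[1:6]), gt)$is_tp)
  # exactly 50% overlap counts as TP
  half <- c(which(gt)[1:2], setdiff(seq_len(prod(d)), which(gt))[1:2])
  lab <- label_tp_fp(mkscore(half), gt)
  expect_equal(lab$overlap_fraction, 0.5)
  expect_true(lab$is_tp)
  # zero overlap is FP
  expect_false(label_tp_fp(mkscore(setdiff(seq_len(prod(d)), which(gt))[1:5]), gt)$is_tp)
})

test_that("per-lesion confidences separate constructed TPs from FPs", {
  # fixture: TP lesions at confidence 0.9, FP lesions at 0.1 => AUC 1
  tp_conf <- rep(0.9, 6)
  fp_conf <- rep(0.1, 8)
  expect_equal(ood_auc(tp_conf, fp_conf, "low_is_ood"), 1)
})

test_that("a small trained ensemble behaves like an uncertainty model", {
  cohort <- generate_cohort(small_spec(lesion_count_range = c(1L, 2L)), 8L,
                            base_seed = 41L)
  cfg <- seg_config(features = c(4L, 8L), epochs = 3L, lr = 3e-3, seed = 2L)
  ens <- train_seg_ensemble(cohort, cfg, n_members = 2L)
  v <- cohort[[1]]
  stack <- predict_prob_stack(v, ens)
  expect_length(stack, 2L)
  expect_true(all(vapply(stack, function(p) all(p >= 0 & p <= 1), logical(1))))
  # members trained on disjoint folds differ somewhere
  expect_gt(max(abs(stack[[1]] - stack[[2]])), 0)
  # certainty map is well-formed and fp_count returns a count
  cert <- voxel_certainty(stack, "ensemble_entropy")
  expect_true(all(cert$values <= 1))
  expect_gte(fp_count(v, ens), 0L)
})

test_that("MC dropout passes are stochastic only when dropout is active", {
  cohort <- generate_cohort(small_spec(lesion_count_range = c(1L, 2L)), 4L,
                            base_seed = 43L)
  m_plain <- train_seg(cohort, seg_config(features = c(4L, 8L), epochs = 2L,
                                          dropout_p = 0, seed = 3L))
  st <- predict_prob_stack(cohort[[1]], m_plain, n_passes = 3L, mc_dropout = TRUE)
  expect_identical(st[[1]], st[[2]])
  expect_identical(st[[2]], st[[3]])
  m_drop <- train_seg(cohort, seg_config(features = c(4L, 8L), epochs = 2L,
                                         dropout_p = 0.5, seed = 3L))
  st2 <- predict_prob_stack(cohort[[1]], m_drop, n_passes = 3L,
                            mc_dropout = TRUE, seed = 7L)
  expect_gt(max(abs(st2[[1]] - st2[[2]])), 0)
  # same seed reproduces the same stochastic passes
  st3 <- predict_prob_stack(cohort[[1]], m_drop, n_passes = 3L,
                            mc_dropout = TRUE, seed = 7L)
  expect_identical(st2, st3)
  # softmax baseline: single grid in [0, 1]
  s1 <- predict_prob_stack(cohort[[1]], m_plain)
  expect_length(s1, 1L)
  expect_true(all(s1[[1]] >= 0 & s1[[1]] <= 1))
})

test_that("cross-entropy training reduces the loss on lesion phantoms", {
  cohort <- generate_cohort(small_spec(lesion_count_range = c(1L, 2L)), 6L,
                            base_seed = 47L)
  m <- train_seg(cohort, seg_config(features = c(4L, 8L), epochs = 4L,
                                    loss = "cross_entropy", lr = 3e-3, seed = 5L))
  expect_lt(m$curve$loss[4], m$curve$loss[1])
  expect_error(train_seg(list(new_volume(array(0, c(8, 8, 8)))), seg_config()),
               "lesion_mask")
})
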