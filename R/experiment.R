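# End-to-end scaled OOD experiment: generate phantom cohorts, train the VQ
# autoencoder and the autoregressive model on clean phantoms, then score
# held-out clean and corrupted phantoms with the sequence log-likelihood and
# the reconstruction-MSE baseline.

#' Run the scaled OOD-detection experiment
#'
#' Trains the full latent-likelihood pipeline on clean phantoms and evaluates
#' per-corruption-class AUCs on held-out volumes, mirroring the benchmark
#' protocol at desk scale: 200 training phantoms of 32^3 voxels, a 2-level
#' VQ with K = 32 codes, and 20 held-out clean vs 20-per-class corrupted
#' volumes.
#'
#' @param n_train,n_test clean training / held-out cohort sizes.
#' @param phantom a [phantom_spec()] defining the in-distribution family.
#' @param suite corruption suite applied to the held-out volumes.
#' @param vq a [vq_config()].
#' @param ar an [ar_config()].
#' @param seed master seed; all cohort, training and corruption seeds derive
#'   from it.
#' @param verbose print stage progress.
#' @return An `ood_experiment`: list with `scores` (score table holding
#'   `loglik`, `mse` and `mse_normalised` per volume), `summary`
#'   (per-class mean/sd/AUC of the log-likelihood), `vq_model`, `ar_model`,
#'   and the configurations used.
#' @export
ood_experiment <- function(n_train = 200L, n_test = 20L,
                           phantom = phantom_spec(),
                           suite = default_corruption_suite(),
                           vq = vq_config(),
                           ar = ar_config(n_layers = 2L, n_heads = 2L,
                                          d_model = 64L, epochs = 6L),
                           seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("generating %d training + %d held-out phantoms", n_train, n_test)
  train_cohort <- generate_cohort(phantom, n_train, base_seed = derive_seed(seed, 1L),
                                  id_prefix = "train")
  test_cohort <- generate_cohort(phantom, n_test, base_seed = derive_seed(seed, 2L),
                                 id_prefix = "test")

  vq$seed <- derive_seed(seed, 3L)
  say("training VQ (levels=%d, K=%d) on %d phantoms", vq$levels, vq$K, n_train)
  vq_model <- train_vq(train_cohort, vq, verbose = verbose)

  say("encoding training cohort and fitting the sequence model")
  train_seqs <- lapply(train_cohort, function(v) flatten_codes(vq_encode(v, vq_model)))
  ar$seed <- derive_seed(seed, 4L)
  ar_model <- train_ar(train_seqs, ar, verbose = verbose)

  score_volume <- function(v, id, group) {
    ll <- sequence_loglik(flatten_codes(vq_encode(v, vq_model)), ar_model)
    rm_ <- reconstruction_mse(v, vq_model)
    tibble::tibble(
      volume_id = id, group_label = group,
      score_name = c("loglik", "mse", "mse_normalised"),
      score_value = c(ll$total_loglik, rm_$mse, rm_$normalised)
    )
  }

  say("scoring %d clean held-out volumes", n_test)
  rows <- purrr::imap(test_cohort, function(v, i) {
    score_volume(v, v$id, "in_distribution")
  })
  for (lab in names(suite)) {
    say("scoring corruption class %s", lab)
    spec <- suite[[lab]]
    rows <- c(rows, purrr::imap(test_cohort, function(v, i) {
      cv <- apply_corruption(v, spec)
      score_volume(cv$volume, paste0(v$id, "_", lab), paste0("near_ood:", lab))
    }))
  }
  scores <- dplyr::bind_rows(rows)
  validate_score_table(scores)

  summary <- summarise_by_class(scores, "loglik", direction = "low_is_ood")

  structure(
    list(scores = scores, summary = summary, vq_model = vq_model,
         ar_model = ar_model, suite = suite, phantom = phantom,
         n_train = n_train, n_test = n_test, seed = seed,
         runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "ood_experiment"
  )
}

#' @export
print.ood_experiment <- function(x, ...) {
  cat(sprintf("<ood_experiment> %d train / %d held-out phantoms, %d corruption classes (%.0f s)\n",
              x$n_train, x$n_test, length(x$suite), x$runtime_s))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Per-class AUC of a fitted experiment for a chosen score
#'
#' @param exp_ an `ood_experiment`.
#' @param score_name `"loglik"`, `"mse"` or `"mse_normalised"`.
#' @param direction score direction (`"low_is_ood"` for loglik,
#'   `"high_is_ood"` for the MSE scores).
#' @return A named numeric vector of AUCs, one per corruption class.
#' @export
experiment_aucs <- function(exp_, score_name = "loglik",
                            direction = if (score_name == "loglik")
                              "low_is_ood" else "high_is_ood") {
  sm <- summarise_by_class(exp_$scores, score_name, direction = direction)
  out <- sm$auc[sm$group_label != "in_distribution"]
  names(out) <- sub("^near_ood:", "", sm$group_label[sm$group_label != "in_distribution"])
  out
}

#' Axial slice range affected by a chunk-deletion corruption
#'
#' @param nz axial extent in voxels.
#' @param location `"central"` or `"upper"`.
#' @param fraction fraction of the extent deleted.
#' @return Integer vector of the deleted slice indices.
#' @export
chunk_slice_range <- function(nz, location = c("central", "upper"),
                              fraction = 0.2) {
  location <- match.arg(location)
  width <- max(1L, as.integer(floor(fraction * nz)))
  start <- if (location == "central") as.integer(floor((nz - width) / 2)) + 1L
  else nz - width + 1L
  start:(start + width - 1L)
}

#' Mean conditional log-probability inside vs outside a slice region
#'
#' Used to check that spatial likelihood maps localise anomalies: for a
#' chunk-deleted volume the mean per-voxel conditional log-probability inside
#' the deleted block should be lower than outside it.
#'
#' @param map spatial likelihood map from [spatial_likelihood_map()] at input
#'   resolution.
#' @param slices axial slice indices of the region (see
#'   [chunk_slice_range()]).
#' @return A list with `inside`, `outside` and `contrast`
#'   (`inside - outside`; negative when the region is flagged).
#' @export
map_region_contrast <- function(map, slices) {
  d <- dim(map)
  abort_if(any(slices < 1L) || any(slices > d[3]), "slices outside the map")
  inside <- mean(map[, , slices])
  outside <- mean(map[, , setdiff(seq_len(d[3]), slices)])
  list(inside = inside, outside = outside, contrast = inside - outside)
}
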