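# Segmentation with uncertainty: a small 3D encoder-decoder with skip fusion,
# trained with Dice or cross-entropy loss, plus the three per-lesion
# uncertainty baselines — softmax probability, deep-ensemble entropy and
# Monte Carlo dropout entropy. Per-lesion certainty is the mean per-voxel
# certainty over each connected component of the majority-vote prediction.

#' Configure a segmentation network
#'
#' The desk-scale backbone is a two-resolution encoder-decoder: full-res
#' convolution, stride-2 downsampling, a mid-level convolution,
#' nearest-neighbour upsampling with a 1x1 skip fusion, dropout, and a
#' convolutional head producing a foreground logit per voxel.
#'
#' @param features integer pair `c(full_res, half_res)` channel widths.
#' @param dropout_p dropout probability in \[0, 1); 0.5 is the Monte Carlo
#'   dropout setting.
#' @param loss `"dice"` (default) or `"cross_entropy"` (used for the softmax
#'   baseline, since Dice-trained probabilities are poorly calibrated).
#' @param lr,epochs,batch_size Adam learning rate and schedule.
#' @param seed integer seed.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(features = c(8L, 16L), dropout_p = 0,
                       loss = c("dice", "cross_entropy"),
                       lr = 1e-3, epochs = 4L, batch_size = 4L, seed = 1L) {
  loss <- match.arg(loss)
  abort_if(length(features) < 2L, "features must give at least two widths")
  abort_if(dropout_p < 0 || dropout_p >= 1, "dropout_p must lie in [0, 1)")
  structure(list(features = as.integer(features[1:2]), dropout_p = dropout_p,
                 loss = loss, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "seg_config")
}

seg_init_params <- function(cfg) {
  f1 <- cfg$features[1]; f2 <- cfg$features[2]
  list(
    enc_W = init_weight(27L, f1), enc_b = numeric(f1),
    down_W = init_weight(27L * f1, f2), down_b = numeric(f2),
    mid_W = init_weight(27L * f2, f2), mid_b = numeric(f2),
    fuse_W = init_weight(f1 + f2, f1), fuse_b = numeric(f1),
    head_W = init_weight(27L * f1, 1L, gain = 1), head_b = numeric(1L)
  )
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  sp <- d[1:3] %/% 2L
  dx <- array(0, dim = c(sp, d[4]))
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    dx <- dx + dy[seq(1L + ox, d[1], 2L), seq(1L + oy, d[2], 2L),
                  seq(1L + oz, d[3], 2L), , drop = FALSE]
  }
  dx
}

seg_forward <- function(x, params, cfg, dropout_active = FALSE,
                        dropout_seed = NULL) {
  x4 <- array(x, dim = c(dim(x), 1L))
  e <- conv3d_forward(x4, params$enc_W, params$enc_b, 3L, 1L, 1L)
  ea <- relu(e$out)
  dn <- conv3d_forward(ea, params$down_W, params$down_b, 3L, 2L, 1L)
  dna <- relu(dn$out)
  md <- conv3d_forward(dna, params$mid_W, params$mid_b, 3L, 1L, 1L)
  mda <- relu(md$out)
  up <- nn_upsample_channels(mda, 2L)
  cat_ <- abind4(ea, up)
  d <- dim(cat_)
  catM <- matrix(cat_, ncol = d[4])
  fz <- sweep(catM %*% params$fuse_W, 2, params$fuse_b, `+`)
  fza <- relu(fz)
  mask <- NULL
  if (dropout_active && cfg$dropout_p > 0) {
    mask <- with_seed(dropout_seed %||% stats::runif(1, 1, 1e8), {
      matrix(stats::runif(length(fza)) >= cfg$dropout_p, nrow(fza), ncol(fza))
    })
    fza <- fza * mask / (1 - cfg$dropout_p)
  }
  fz_arr <- array(fza, dim = c(d[1:3], ncol(fza)))
  hd <- conv3d_forward(fz_arr, params$head_W, params$head_b, 3L, 1L, 1L)
  logits <- array(hd$out, dim = d[1:3])
  list(logits = logits, prob = sigmoid(logits),
       e = e, ea = ea, dn = dn, dna = dna, md = md, mda = mda,
       catM = catM, fz = fz, mask = mask, hd = hd, cat_dim = d)
}

nn_upsample_channels <- function(arr, factor) {
  d <- dim(arr)
  idx <- c(lapply(d[1:3], function(n) rep(seq_len(n), each = factor)),
           list(seq_len(d[4])))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

seg_backward <- function(dlogits, fwd, params, cfg) {
  g <- list()
  hb <- conv3d_backward(array(dlogits, dim = c(dim(dlogits), 1L)), fwd$hd,
                        params$head_W)
  g$head_W <- hb$dW; g$head_b <- hb$db
  d <- fwd$cat_dim
  dfza <- matrix(hb$dx, ncol = dim(hb$dx)[4])
  if (!is.null(fwd$mask)) dfza <- dfza * fwd$mask / (1 - cfg$dropout_p)
  dfz <- relu_backward(dfza, fwd$fz)
  g$fuse_W <- crossprod(fwd$catM, dfz)
  g$fuse_b <- colSums(dfz)
  dcat <- array(dfz %*% t(params$fuse_W), dim = d)
  f1 <- cfg$features[1]
  dea_skip <- dcat[, , , seq_len(f1), drop = FALSE]
  dup <- dcat[, , , f1 + seq_len(d[4] - f1), drop = FALSE]
  dmda <- upsample2_backward(dup)
  dmd <- relu_backward(dmda, fwd$md$out)
  mb <- conv3d_backward(dmd, fwd$md, params$mid_W)
  g$mid_W <- mb$dW; g$mid_b <- mb$db
  ddna <- relu_backward(mb$dx, fwd$dn$out)
  db_ <- conv3d_backward(ddna, fwd$dn, params$down_W)
  g$down_W <- db_$dW; g$down_b <- db_$db
  dea <- dea_skip + db_$dx
  de <- relu_backward(dea, fwd$e$out)
  eb <- conv3d_backward(de, fwd$e, params$enc_W, need_dx = FALSE)
  g$enc_W <- eb$dW; g$enc_b <- eb$db
  g
}

#' Train a segmentation network on phantoms with lesion masks
#'
#' @param cohort list of `volume` objects carrying `lesion_mask`.
#' @param cfg a [seg_config()].
#' @param verbose print per-epoch loss.
#' @return A `seg_model`.
#' @export
train_seg <- function(cohort, cfg = seg_config(), verbose = FALSE) {
  abort_if(length(cohort) == 0, "cohort must be non-empty")
  abort_if(any(vapply(cohort, function(v) is.null(v$lesion_mask), logical(1))),
           "all training volumes need a lesion_mask")
  set.seed(cfg$seed)
  params <- seg_init_params(cfg)
  opt <- adam_init(params)
  n <- length(cohort)
  curve <- numeric(cfg$epochs)
  eps <- 1e-6
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      acc <- list()
      for (i in batch) {
        v <- cohort[[i]]
        gt <- as.numeric(v$lesion_mask)
        fwd <- seg_forward(v$intensities, params, cfg,
                           dropout_active = cfg$dropout_p > 0,
                           dropout_seed = derive_seed(cfg$seed, epoch * 10000L + i))
        p <- as.numeric(fwd$prob)
        if (cfg$loss == "dice") {
          num <- 2 * sum(p * gt) + eps
          den <- sum(p) + sum(gt) + eps
          loss <- 1 - num / den
          dp <- -(2 * gt * den - num) / den^2
        } else {
          Nv <- length(p)
          loss <- -mean(gt * log(pmax(p, 1e-12)) + (1 - gt) * log(pmax(1 - p, 1e-12)))
          dp <- (p - gt) / pmax(p * (1 - p), 1e-12) / Nv
        }
        dlogits <- array(dp * p * (1 - p), dim = dim(fwd$logits))
        acc <- accum_grads(acc, seg_backward(dlogits, fwd, params, cfg))
        ep_loss <- ep_loss + loss
      }
      acc <- scale_grads(acc, 1 / length(batch))
      st <- adam_step(params, acc, opt, lr = cfg$lr)
      params <- st$params; opt <- st$state
    }
    curve[epoch] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d: %s loss %.4f", epoch, cfg$loss, curve[epoch]))
  }
  structure(list(params = params, cfg = cfg, trained = TRUE,
                 curve = tibble::tibble(epoch = seq_len(cfg$epochs), loss = curve)),
            class = "seg_model")
}

#' Train a deep ensemble of segmentation networks
#'
#' Each member has the same architecture but its own seed and its own subset
#' of the training data (disjoint folds when `disjoint = TRUE`).
#'
#' @param cohort training volumes with lesion masks.
#' @param cfg base [seg_config()].
#' @param n_members ensemble size N (default 5).
#' @param disjoint train each member on a disjoint fold.
#' @return A `seg_ensemble` (list of `seg_model`s).
#' @export
train_seg_ensemble <- function(cohort, cfg = seg_config(), n_members = 5L,
                               disjoint = TRUE) {
  abort_if(n_members < 1L, "n_members must be >= 1")
  folds <- if (disjoint && length(cohort) >= n_members) {
    split(seq_along(cohort), rep_len(seq_len(n_members), length(cohort)))
  } else {
    rep(list(seq_along(cohort)), n_members)
  }
  members <- lapply(seq_len(n_members), function(m) {
    cfg_m <- cfg
    cfg_m$seed <- derive_seed(cfg$seed, m)
    train_seg(cohort[folds[[m]]], cfg_m)
  })
  structure(members, class = "seg_ensemble")
}

#' Per-voxel foreground-probability stack
#'
#' Produces the N probability grids that the uncertainty measures aggregate:
#' one per ensemble member, or one per stochastic forward pass with dropout
#' active at inference (Monte Carlo dropout), or a single softmax map.
#'
#' @param v a `volume`.
#' @param model a `seg_model` or `seg_ensemble`.
#' @param n_passes number of stochastic passes for MC dropout (default 5);
#'   ignored for ensembles (one pass per member).
#' @param mc_dropout keep dropout active at inference (single models only).
#' @param seed seed for the stochastic passes.
#' @return A list of 3D probability arrays in \[0, 1\].
#' @export
predict_prob_stack <- function(v, model, n_passes = 5L, mc_dropout = FALSE,
                               seed = 1L) {
  if (inherits(model, "seg_ensemble")) {
    return(lapply(model, function(m) {
      seg_forward(v$intensities, m$params, m$cfg, dropout_active = FALSE)$prob
    }))
  }
  abort_if(!inherits(model, "seg_model") || !isTRUE(model$trained),
           "model must be a trained seg_model or seg_ensemble")
  if (!mc_dropout || model$cfg$dropout_p == 0) {
    n <- if (mc_dropout) n_passes else 1L
    one <- seg_forward(v$intensities, model$params, model$cfg,
                       dropout_active = FALSE)$prob
    return(rep(list(one), n))
  }
  lapply(seq_len(n_passes), function(i) {
    seg_forward(v$intensities, model$params, model$cfg, dropout_active = TRUE,
                dropout_seed = derive_seed(seed, i))$prob
  })
}

#' Per-voxel certainty map from a probability stack
#'
#' For the entropy methods the N foreground probabilities are averaged to a
#' mean class distribution (p̄, 1-p̄) per voxel; the binary entropy
#' H = -p̄ ln p̄ - (1-p̄) ln(1-p̄) is subtracted from 1 so that larger values
#' mean higher certainty (maximum 1, and 1 - ln 2 at p̄ = 0.5). For the
#' softmax baseline the certainty is the foreground probability itself.
#'
#' @param stack list of probability arrays from [predict_prob_stack()].
#' @param method `"softmax"`, `"ensemble_entropy"` or `"dropout_entropy"`.
#' @return A `certainty_map`: list with `values` (array) and `method`.
#' @export
voxel_certainty <- function(stack, method = c("ensemble_entropy",
                                              "dropout_entropy", "softmax")) {
  method <- match.arg(method)
  abort_if(length(stack) == 0, "stack must be non-empty")
  rng <- range(unlist(lapply(stack, range)))
  abort_if(rng[1] < 0 || rng[2] > 1, "probabilities must lie in [0, 1]")
  pbar <- Reduce(`+`, stack) / length(stack)
  values <- if (method == "softmax") {
    pbar
  } else {
    xlx <- function(p) ifelse(p > 0, p * log(p), 0)
    H <- -(xlx(pbar) + xlx(1 - pbar))
    1 - H
  }
  structure(list(values = values, method = method), class = "certainty_map")
}

#' Majority-vote prediction from a probability stack
#'
#' Each member's probabilities are thresholded at 0.5; a voxel is foreground
#' when more than half the members vote for it.
#'
#' @param stack list of probability arrays.
#' @param threshold per-member foreground threshold.
#' @return A logical array.
#' @export
majority_vote <- function(stack, threshold = 0.5) {
  votes <- Reduce(`+`, lapply(stack, function(p) p >= threshold))
  votes > length(stack) / 2
}

# 26-connectivity component labelling on a logical 3D array via igraph.
half_offsets_26 <- function() {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  off[off$dz > 0 | (off$dz == 0 & (off$dy > 0 | (off$dy == 0 & off$dx > 0))), ]
}

#' Connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (default) or 6.
#' @return A list of integer vectors, each the linear voxel indices of one
#'   component, ordered by first voxel.
#' @export
connected_components_3d <- function(mask, connectivity = 26L) {
  abort_if(!connectivity %in% c(6L, 26L), "connectivity must be 6 or 26")
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0) return(list())
  pos <- array(0L, dim = d)
  pos[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  offs <- half_offsets_26()
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  }
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- coords + matrix(as.integer(offs[r, ]), nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nidx <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- pos[nidx] > 0L
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <- cbind(pos[fg[ok]][hit], pos[nidx][hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  memb <- igraph::components(g)$membership
  unname(split(fg, memb))
}

#' Per-lesion certainty scores
#'
#' Lesions are the connected components of the majority-vote prediction; each
#' lesion's confidence is the mean per-voxel certainty over its voxels.
#'
#' @param cert a [voxel_certainty()] map.
#' @param stack the probability stack the certainty came from.
#' @param connectivity component connectivity (26 or 6).
#' @param threshold per-member foreground threshold for the vote.
#' @return A tibble with `component_id`, `n_voxels`, `confidence`, `is_tp`
#'   (NA until [label_tp_fp()]) and a `voxels` list-column of linear indices.
#'   Empty predictions give a zero-row tibble.
#' @export
lesion_scores <- function(cert, stack, connectivity = 26L, threshold = 0.5) {
  pred <- majority_vote(stack, threshold)
  abort_if(!all(dim(pred) == dim(cert$values)),
           "certainty map and predictions must be aligned")
  comps <- connected_components_3d(pred, connectivity)
  tibble::tibble(
    component_id = seq_along(comps),
    n_voxels = vapply(comps, length, integer(1)),
    confidence = vapply(comps, function(ix) mean(cert$values[ix]), numeric(1)),
    is_tp = rep(NA, length(comps)),
    voxels = comps
  )
}

#' Label predicted lesions as true or false positives
#'
#' A predicted component is a true positive when at least 50% of its voxels
#' overlap the ground-truth mask (the overlap fraction is computed over the
#' predicted component, and exactly 50% counts as a TP).
#'
#' @param scores a [lesion_scores()] tibble.
#' @param gt_mask logical ground-truth lesion mask.
#' @return The tibble with `is_tp` and `overlap_fraction` filled in.
#' @export
label_tp_fp <- function(scores, gt_mask) {
  ov <- vapply(scores$voxels, function(ix) mean(gt_mask[ix]), numeric(1))
  scores$overlap_fraction <- ov
  scores$is_tp <- ov >= 0.5
  scores
}

#' Count false-positive lesions on a volume
#'
#' Poor segmentation behaviour is summarised as the number of predicted
#' components that fail the 50% overlap criterion against the ground truth.
#'
#' @param v a `volume`.
#' @param model a `seg_model` or `seg_ensemble`.
#' @param gt_mask logical ground-truth mask (defaults to `v$lesion_mask`).
#' @param ... passed to [predict_prob_stack()].
#' @return Integer count of FP components.
#' @export
fp_count <- function(v, model, gt_mask = v$lesion_mask, ...) {
  abort_if(is.null(gt_mask), "a ground-truth mask is required")
  stack <- predict_prob_stack(v, model, ...)
  method <- if (inherits(model, "seg_ensemble")) "ensemble_entropy" else "softmax"
  cert <- voxel_certainty(stack, method)
  sc <- lesion_scores(cert, stack)
  if (nrow(sc) == 0) return(0L)
  sc <- label_tp_fp(sc, gt_mask)
  sum(!sc$is_tp)
}
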