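# Training and user-facing API for the VQ autoencoder.

vq_pad_volume <- function(x, ls) {
  if (all(ls$padded_shape == dim(x))) return(x)
  out <- array(0, dim = ls$padded_shape)
  lo <- ls$pad_lo
  d <- dim(x)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- x
  out
}

vq_crop_volume <- function(x, ls, orig_shape) {
  if (all(ls$padded_shape == orig_shape)) return(x)
  lo <- ls$pad_lo
  x[lo[1] + seq_len(orig_shape[1]), lo[2] + seq_len(orig_shape[2]),
    lo[3] + seq_len(orig_shape[3]), drop = FALSE]
}

#' Fixed random convolutional feature extractor
#'
#' A frozen, seeded single-layer 3D convolution with ReLU, usable as the
#' perceptual-loss feature extractor. Random convolutional features preserve
#' local structure information and give the perceptual term something
#' meaningful to compare without any pretrained weights.
#'
#' @param channels number of random filters.
#' @param seed seed for the filter weights.
#' @return A `feature_extractor`: list with `forward(x)` and
#'   `backward(dfeat, cache)` functions.
#' @export
random_conv_extractor <- function(channels = 4L, seed = 1L) {
  W <- with_seed(seed, init_weight(27L, channels))
  b <- numeric(channels)
  structure(list(
    forward = function(x) {
      cv <- conv3d_forward(array(x, dim = c(dim(x), 1L)), W, b, 3L, 2L, 1L)
      list(features = relu(cv$out), cache = cv)
    },
    backward = function(dfeat, cache) {
      da <- relu_backward(dfeat, cache$out)
      bk <- conv3d_backward(da, cache, W)
      array(bk$dx, dim = dim(bk$dx)[1:3])
    }
  ), class = "feature_extractor")
}

# Patch-style discriminator: two stride-2 convolutions + 1x1 head, hinge loss.
disc_init_params <- function() {
  list(d1_W = init_weight(27L, 8L), d1_b = numeric(8L),
       d2_W = init_weight(27L * 8L, 16L), d2_b = numeric(16L),
       d3_W = init_weight(16L, 1L, gain = 1), d3_b = numeric(1L))
}

disc_forward <- function(x, p) {
  c1 <- conv3d_forward(array(x, dim = c(dim(x), 1L)), p$d1_W, p$d1_b, 3L, 2L, 1L)
  a1 <- lrelu(c1$out)
  c2 <- conv3d_forward(a1, p$d2_W, p$d2_b, 3L, 2L, 1L)
  a2 <- lrelu(c2$out)
  d <- dim(a2)
  aM <- matrix(a2, ncol = d[4])
  logits <- sweep(aM %*% p$d3_W, 2, p$d3_b, `+`)
  list(logits = as.vector(logits), c1 = c1, a1 = a1, c2 = c2, a2 = a2, aM = aM,
       map_dim = d)
}

disc_backward <- function(dlogits, fwd, p, need_dx = FALSE) {
  g <- list()
  dlM <- matrix(dlogits, ncol = 1L)
  g$d3_W <- crossprod(fwd$aM, dlM)
  g$d3_b <- sum(dlM)
  da2 <- array(dlM %*% t(p$d3_W), dim = fwd$map_dim)
  da2 <- lrelu_backward(da2, fwd$c2$out)
  b2 <- conv3d_backward(da2, fwd$c2, p$d2_W)
  g$d2_W <- b2$dW; g$d2_b <- b2$db
  da1 <- lrelu_backward(b2$dx, fwd$c1$out)
  b1 <- conv3d_backward(da1, fwd$c1, p$d1_W, need_dx = need_dx)
  g$d1_W <- b1$dW; g$d1_b <- b1$db
  dx <- if (need_dx) array(b1$dx, dim = dim(b1$dx)[1:3]) else NULL
  list(grads = g, dx = dx)
}

#' Reconstruction loss breakdown
#'
#' Components: `mse` (mean squared voxel difference), `spectral` (mean squared
#' modulus of the difference of the discrete Fourier transforms, divided by
#' voxel count — by Parseval's identity this equals the plain MSE for
#' real-valued inputs, so it is reported for monitoring and its gradient is
#' shared with the MSE), `perceptual` (mean squared feature difference under
#' `cfg$perceptual_extractor`; 0 when unset), `commitment`
#' (`beta *` mean squared distance between latents and their assigned
#' codebook entries), `adversarial` (0 outside the training loop), and
#' `total` (the weighted sum).
#'
#' @param x original intensities (3D array or `volume`).
#' @param xhat reconstruction (3D array or `volume`).
#' @param latents pre-quantisation latent array (last dim = embedding dim).
#' @param indices 0-based codebook assignments for `latents`.
#' @param cb the `codebook`.
#' @param cfg the [vq_config()] supplying weights and the extractor.
#' @return Named list of loss components including `total`.
#' @export
vq_loss <- function(x, xhat, latents, indices, cb, cfg) {
  if (inherits(x, "volume")) x <- x$intensities
  if (inherits(xhat, "volume")) xhat <- xhat$intensities
  abort_if(!all(dim(x) == dim(xhat)), "x and xhat must share a shape")
  d <- x - xhat
  n_vox <- length(x)
  mse <- mean(d^2)
  spectral <- mean(Mod(stats::fft(xhat) - stats::fft(x))^2) / n_vox
  perceptual <- 0
  w <- cfg$loss_weights
  if (w[["perceptual"]] > 0 && !is.null(cfg$perceptual_extractor)) {
    fx <- cfg$perceptual_extractor$forward(x)
    fxh <- cfg$perceptual_extractor$forward(xhat)
    perceptual <- mean((fx$features - fxh$features)^2)
  }
  commitment <- 0
  if (!is.null(latents)) {
    zM <- as_latent_matrix(latents, cb$n)
    e <- cb$entries[as.integer(indices) + 1L, , drop = FALSE]
    commitment <- cfg$beta * mean((zM - e)^2)
  }
  adversarial <- 0
  total <- w[["mse"]] * mse + w[["spectral"]] * spectral +
    w[["perceptual"]] * perceptual + w[["adversarial"]] * adversarial +
    commitment
  list(mse = mse, spectral = spectral, perceptual = perceptual,
       commitment = commitment, adversarial = adversarial, total = total)
}

#' Train a vector-quantising autoencoder on a cohort of volumes
#'
#' Encoder/decoder weights are learned with Adam against the weighted loss of
#' [vq_loss()]; the codebook is learned by EMA over assigned latents
#' (no gradient flows into it), and the encoder receives straight-through
#' gradients through the quantisation step plus the commitment term.
#'
#' @param cohort list of `volume` objects (or bare 3D arrays) with a common
#'   shape.
#' @param cfg a [vq_config()].
#' @param verbose print per-epoch loss summaries.
#' @return A `vq_model`: list with `params`, `codebook`, `cfg`, `input_shape`,
#'   `ls` (latent-shape bookkeeping), `curve` (per-epoch loss tibble) and,
#'   when `cfg$use_gan`, the discriminator parameters.
#' @export
train_vq <- function(cohort, cfg = vq_config(), verbose = FALSE) {
  abort_if(length(cohort) == 0, "cohort must be non-empty")
  xs <- lapply(cohort, function(v) if (inherits(v, "volume")) v$intensities else v)
  shape <- dim(xs[[1]])
  abort_if(!all(vapply(xs, function(x) all(dim(x) == shape), logical(1))),
           "all volumes must share a shape")
  ls <- latent_shape(shape, cfg$levels)
  xs <- lapply(xs, vq_pad_volume, ls = ls)
  n_vox <- prod(ls$padded_shape)

  set.seed(cfg$seed)
  params <- vq_init_params(cfg)
  cb <- new_codebook(cfg$K, cfg$n, seed = derive_seed(cfg$seed, 1L))
  opt <- adam_init(params)
  disc <- NULL; disc_opt <- NULL
  if (cfg$use_gan) {
    disc <- disc_init_params()
    disc_opt <- adam_init(disc)
  }
  w <- cfg$loss_weights
  use_perc <- w[["perceptual"]] > 0 && !is.null(cfg$perceptual_extractor)
  n <- length(xs)
  curve <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep <- c(mse = 0, spectral = 0, perceptual = 0, commitment = 0,
            adversarial = 0, total = 0)
    for (batch in batches) {
      acc <- list()
      batch_z <- vector("list", length(batch))
      batch_idx <- vector("list", length(batch))
      disc_acc <- list()
      for (bi in seq_along(batch)) {
        x <- xs[[batch[bi]]]
        enc <- vq_encode_forward(array(x, dim = c(dim(x), 1L)), params, cfg)
        ze <- enc$ze
        zM <- matrix(ze, ncol = cfg$n)
        idx <- vq_quantize(zM, cb)
        e <- cb$entries[idx + 1L, , drop = FALSE]
        zq <- array(zM + (e - zM), dim = dim(ze)) # straight-through values
        dec <- vq_decode_forward(zq, params, cfg)
        xhat <- dec$xhat
        dvox <- xhat - x
        mse <- mean(dvox^2)
        spectral <- mse # Parseval: full-DFT L2 / N == voxel MSE
        commitment <- cfg$beta * mean((zM - e)^2)
        perc <- 0
        dxhat <- (w[["mse"]] + w[["spectral"]]) * 2 * dvox / n_vox
        if (use_perc) {
          fx <- cfg$perceptual_extractor$forward(x)
          fxh <- cfg$perceptual_extractor$forward(xhat)
          fd <- fxh$features - fx$features
          perc <- mean(fd^2)
          dxhat <- dxhat + w[["perceptual"]] *
            cfg$perceptual_extractor$backward(2 * fd / length(fd), fxh$cache)
        }
        adv <- 0
        if (cfg$use_gan) {
          dfx <- disc_forward(x, disc)
          dfxh <- disc_forward(xhat, disc)
          np <- length(dfxh$logits)
          adv <- -mean(dfxh$logits)
          gen_b <- disc_backward(rep(-w[["adversarial"]] / np, np), dfxh, disc,
                                 need_dx = TRUE)
          dxhat <- dxhat + gen_b$dx
          # hinge loss for the discriminator on (real, fake) pair
          dreal <- -as.numeric(1 - dfx$logits > 0) / np
          dfake <- as.numeric(1 + dfxh$logits > 0) / np
          disc_acc <- accum_grads(disc_acc, disc_backward(dreal, dfx, disc)$grads)
          disc_acc <- accum_grads(disc_acc, disc_backward(dfake, dfxh, disc)$grads)
        }
        dec_b <- vq_decode_backward(dxhat, dec, params, cfg)
        dze <- dec_b$dzq +
          array(cfg$beta * 2 * (zM - e) / length(zM), dim = dim(ze))
        enc_g <- vq_encode_backward(dze, enc, params, cfg)
        acc <- accum_grads(acc, dec_b$grads)
        acc <- accum_grads(acc, enc_g)
        batch_z[[bi]] <- zM
        batch_idx[[bi]] <- idx
        total <- w[["mse"]] * mse + w[["spectral"]] * spectral +
          w[["perceptual"]] * perc + w[["adversarial"]] * adv + commitment
        ep <- ep + c(mse, spectral, perc, commitment, adv, total)
      }
      acc <- scale_grads(acc, 1 / length(batch))
      st <- adam_step(params, acc, opt, lr = cfg$lr)
      params <- st$params; opt <- st$state
      if (cfg$use_gan && length(disc_acc)) {
        disc_acc <- scale_grads(disc_acc, 1 / length(batch))
        dst <- adam_step(disc, disc_acc, disc_opt, lr = cfg$lr)
        disc <- dst$params; disc_opt <- dst$state
      }
      zall <- do.call(rbind, batch_z)
      cb <- vq_ema_update(cb, zall, unlist(batch_idx), cfg$ema_decay, cfg$ema_eps)
      # restart dead codes on random batch latents so the codebook stays used
      dead <- which(cb$ema_counts < 0.05 * sum(cb$ema_counts) / cfg$K)
      if (length(dead)) {
        pick <- sample.int(nrow(zall), length(dead), replace = TRUE)
        cb$entries[dead, ] <- zall[pick, , drop = FALSE]
        cb$ema_sums[dead, ] <- cb$entries[dead, , drop = FALSE]
        cb$ema_counts[dead] <- 1
      }
    }
    curve[[epoch]] <- tibble::as_tibble(c(list(epoch = epoch), as.list(ep / n)))
    if (verbose) {
      message(sprintf("epoch %d: mse %.5f commit %.5f total %.5f",
                      epoch, ep[["mse"]] / n, ep[["commitment"]] / n,
                      ep[["total"]] / n))
    }
  }

  structure(
    list(cfg = cfg, params = params, codebook = cb, input_shape = shape,
         ls = ls, curve = dplyr::bind_rows(curve), disc = disc),
    class = "vq_model"
  )
}

#' @export
print.vq_model <- function(x, ...) {
  cat(sprintf("<vq_model> %d levels, K=%d, n=%d; input %s -> latent %s (%d tokens)\n",
              x$cfg$levels, x$cfg$K, x$cfg$n,
              paste(x$input_shape, collapse = "x"),
              paste(x$ls$latent_shape, collapse = "x"),
              x$ls$sequence_length))
  if (nrow(x$curve)) {
    last <- x$curve[nrow(x$curve), ]
    cat(sprintf("  final epoch: mse %.5f, total %.5f\n", last$mse, last$total))
  }
  invisible(x)
}

#' Encode a volume to a grid of codebook indices
#'
#' @param v a `volume` or 3D array with the shape the model was trained on.
#' @param model a trained [train_vq()] model.
#' @return A `code_grid`: list with `indices` (0-based integer array of the
#'   latent shape), `latent_shape`, `K` and the codebook `entries` it indexes.
#' @export
vq_encode <- function(v, model) {
  x <- if (inherits(v, "volume")) v$intensities else v
  abort_if(!all(dim(x) == model$input_shape),
           "volume shape does not match the model's input shape")
  x <- vq_pad_volume(x, model$ls)
  enc <- vq_encode_forward(array(x, dim = c(dim(x), 1L)), model$params, model$cfg)
  idx <- vq_quantize(enc$ze, model$codebook)
  new_code_grid(idx, model$cfg$K, model$codebook$entries)
}

new_code_grid <- function(indices, K, entries) {
  abort_if(any(indices < 0L) || any(indices >= K),
           "code indices must lie in [0, K)")
  structure(list(indices = indices, latent_shape = dim(indices),
                 K = as.integer(K), entries = entries),
            class = "code_grid")
}

#' @export
print.code_grid <- function(x, ...) {
  cat(sprintf("<code_grid> %s, K=%d, %d distinct codes used\n",
              paste(x$latent_shape, collapse = "x"), x$K,
              length(unique(as.vector(x$indices)))))
  invisible(x)
}

#' Decode a code grid back to a volume
#'
#' @param cg a `code_grid` from [vq_encode()].
#' @param model the `vq_model` that produced it.
#' @return A `volume` with the model's input shape.
#' @export
vq_decode <- function(cg, model) {
  abort_if(!all(dim(cg$indices) == model$ls$latent_shape),
           "code grid shape does not match the model's latent shape")
  zq <- array(model$codebook$entries[as.vector(cg$indices) + 1L, ],
              dim = c(dim(cg$indices), model$cfg$n))
  dec <- vq_decode_forward(zq, model$params, model$cfg)
  out <- vq_crop_volume(dec$xhat, model$ls, model$input_shape)
  new_volume(array(out, dim = model$input_shape))
}

#' Reconstruction-error OOD score
#'
#' The mean squared error between a volume and its VQ reconstruction, plus the
#' mean-intensity-normalised variant (MSE divided by the volume's mean
#' intensity). High values indicate poor reconstruction.
#'
#' @param v a `volume` or 3D array.
#' @param model a trained `vq_model`.
#' @return List with `mse`, `normalised`, `mean_intensity`,
#'   `normalised_defined` (FALSE when the mean intensity is 0, in which case
#'   `normalised` is `NA` and a warning is raised).
#' @export
reconstruction_mse <- function(v, model) {
  x <- if (inherits(v, "volume")) v$intensities else v
  recon <- vq_decode(vq_encode(x, model), model)$intensities
  mse <- mean((x - recon)^2)
  mi <- mean(x)
  if (mi == 0) {
    warning("mean intensity is 0; normalised MSE undefined")
    list(mse = mse, normalised = NA_real_, mean_intensity = mi,
         normalised_defined = FALSE)
  } else {
    list(mse = mse, normalised = mse / mi, mean_intensity = mi,
         normalised_defined = TRUE)
  }
}
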