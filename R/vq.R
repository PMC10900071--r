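# Vector-quantising autoencoder. The encoder halves each spatial dimension
# per level (stride-2 convolution + residual block), projects to an
# n-dimensional embedding per latent cell, and snaps each embedding to its
# L2-nearest codebook entry. The decoder mirrors the encoder with stride-2
# transposed convolutions. The codebook is learned by exponential moving
# average over the latents assigned to each entry; the encoder receives
# straight-through gradients plus a commitment term.

#' Configure a vector-quantising autoencoder
#'
#' @param levels number of stride-2 downsampling stages (>= 0).
#' @param K codebook size (>= 2).
#' @param n embedding dimension of each codebook entry.
#' @param widths channel width after each level (length `levels`).
#' @param loss_weights named weights for `mse`, `spectral`, `perceptual`,
#'   `adversarial`. The commitment weight is `beta`.
#' @param beta commitment loss weight (0.25, the standard VQ-VAE choice).
#' @param ema_decay EMA decay for codebook updates, in (0, 1).
#' @param ema_eps Laplace smoothing constant for EMA counts.
#' @param use_gan add a patch discriminator trained with a hinge loss and an
#'   adversarial term on reconstructions.
#' @param perceptual_extractor optional feature extractor (see
#'   [random_conv_extractor()]); used when `loss_weights["perceptual"] > 0`.
#' @param lr,epochs,batch_size Adam learning rate and training schedule.
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @return An object of class `vq_config`.
#' @export
vq_config <- function(levels = 2L, K = 32L, n = 8L, widths = NULL,
                      loss_weights = c(mse = 1, spectral = 0,
                                       perceptual = 0, adversarial = 0),
                      beta = 0.25, ema_decay = 0.99, ema_eps = 1e-5,
                      use_gan = FALSE, perceptual_extractor = NULL,
                      lr = 3e-3, epochs = 6L, batch_size = 2L, seed = 1L) {
  levels <- as.integer(levels)
  abort_if(levels < 0L, "levels must be >= 0")
  abort_if(K < 2L, "codebook size K must be >= 2")
  if (is.null(widths)) widths <- if (levels > 0) 8L * 2L^(seq_len(levels) - 1L) else integer(0)
  abort_if(length(widths) != levels, "widths must have one entry per level")
  w <- c(mse = 0, spectral = 0, perceptual = 0, adversarial = 0)
  w[names(loss_weights)] <- loss_weights
  abort_if(any(w < 0) || beta < 0, "loss weights must be >= 0")
  abort_if(ema_decay <= 0 || ema_decay >= 1, "ema_decay must lie in (0, 1)")
  structure(
    list(levels = levels, K = as.integer(K), n = as.integer(n),
         widths = as.integer(widths), loss_weights = w, beta = beta,
         ema_decay = ema_decay, ema_eps = ema_eps, use_gan = use_gan,
         perceptual_extractor = perceptual_extractor,
         lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "vq_config"
  )
}

#' Latent grid shape after stride-2 downsampling
#'
#' Inputs whose dimensions are not divisible by `2^levels` are symmetrically
#' zero-padded up to the next multiple before encoding; the returned
#' `padded_shape` records the extent actually encoded.
#'
#' @param input_shape integer vector of spatial dimensions (2D or 3D).
#' @param levels number of stride-2 stages.
#' @return A list with `latent_shape`, `sequence_length`, `padded_shape`,
#'   `pad_lo` (per-axis low-side padding).
#' @export
#' @examples
#' latent_shape(c(176, 208, 176), 4) # 11 x 13 x 11 grid, 1573 tokens
latent_shape <- function(input_shape, levels) {
  f <- as.integer(2^as.integer(levels))
  padded <- as.integer(ceiling(input_shape / f) * f)
  lat <- padded %/% f
  list(latent_shape = lat, sequence_length = as.integer(prod(lat)),
       padded_shape = padded, pad_lo = as.integer((padded - input_shape) %/% 2))
}

#' Create a codebook
#'
#' EMA statistics start at `counts = 1`, `sums = entries`, so entries that
#' receive no assignments in a batch decay toward themselves (i.e. stay
#' unchanged).
#'
#' @param K number of entries (>= 2).
#' @param n entry dimension.
#' @param seed seed for the Gaussian initialisation.
#' @return An object of class `codebook`.
#' @export
new_codebook <- function(K, n, seed = 1L) {
  entries <- with_seed(seed, matrix(stats::rnorm(K * n, sd = 0.5), K, n))
  structure(list(entries = entries, K = as.integer(K), n = as.integer(n),
                 ema_counts = rep(1, K), ema_sums = entries),
            class = "codebook")
}

as_latent_matrix <- function(latents, n) {
  if (is.matrix(latents)) {
    abort_if(ncol(latents) != n, "latent dimension does not match codebook")
    return(latents)
  }
  d <- dim(latents)
  abort_if(d[length(d)] != n, "latent dimension does not match codebook")
  matrix(latents, ncol = n)
}

#' Quantise latent vectors against a codebook
#'
#' Each latent vector is replaced by the index (0-based) of its nearest
#' codebook entry under squared Euclidean distance; ties break to the lowest
#' index.
#'
#' @param latents array whose last dimension is the embedding dimension, or a
#'   matrix with one latent per row.
#' @param cb a [new_codebook()].
#' @return An integer vector/array of 0-based codebook indices with the
#'   spatial shape of `latents`.
#' @export
vq_quantize <- function(latents, cb) {
  z <- as_latent_matrix(latents, cb$n)
  d2 <- outer(rowSums(z^2), rep(1, cb$K)) - 2 * z %*% t(cb$entries) +
    matrix(rowSums(cb$entries^2), nrow(z), cb$K, byrow = TRUE)
  idx <- max.col(-d2, ties.method = "first") - 1L
  if (!is.matrix(latents)) {
    d <- dim(latents)
    idx <- array(idx, dim = d[-length(d)])
  }
  idx
}

#' EMA codebook update
#'
#' Counts and sums decay with factor `decay` toward the batch statistics of
#' the assigned latents; entries are re-estimated as Laplace-smoothed
#' `sums / counts`.
#'
#' @param cb a `codebook`.
#' @param latents latents of the batch (array or matrix).
#' @param assignments 0-based indices from [vq_quantize()] on the same batch.
#' @param decay EMA decay in (0, 1); 0 reduces to plain batch cluster means.
#' @param eps Laplace smoothing constant.
#' @return The updated `codebook`.
#' @export
vq_ema_update <- function(cb, latents, assignments, decay = 0.99, eps = 1e-5) {
  z <- as_latent_matrix(latents, cb$n)
  idx <- as.integer(assignments) + 1L
  bc <- tabulate(idx, nbins = cb$K)
  bs <- matrix(0, cb$K, cb$n)
  agg <- rowsum(z, group = idx)
  bs[as.integer(rownames(agg)), ] <- agg
  cb$ema_counts <- decay * cb$ema_counts + (1 - decay) * bc
  cb$ema_sums <- decay * cb$ema_sums + (1 - decay) * bs
  N <- sum(cb$ema_counts)
  smoothed <- (cb$ema_counts + eps) / (N + cb$K * eps) * N
  cb$entries <- cb$ema_sums / smoothed
  cb
}

# --- encoder / decoder ------------------------------------------------------

vq_init_params <- function(cfg) {
  p <- list()
  cin <- 1L
  for (l in seq_len(cfg$levels)) {
    cout <- cfg$widths[l]
    p[[sprintf("enc%d_down_W", l)]] <- init_weight(27L * cin, cout)
    p[[sprintf("enc%d_down_b", l)]] <- numeric(cout)
    p[[sprintf("enc%d_res1_W", l)]] <- init_weight(27L * cout, cout)
    p[[sprintf("enc%d_res1_b", l)]] <- numeric(cout)
    p[[sprintf("enc%d_res2_W", l)]] <- init_weight(27L * cout, cout)
    p[[sprintf("enc%d_res2_b", l)]] <- numeric(cout)
    cin <- cout
  }
  p[["enc_proj_W"]] <- init_weight(cin, cfg$n, gain = 1)
  p[["enc_proj_b"]] <- numeric(cfg$n)
  p[["dec_proj_W"]] <- init_weight(cfg$n, cin, gain = 1)
  p[["dec_proj_b"]] <- numeric(cin)
  for (l in rev(seq_len(cfg$levels))) {
    cout <- if (l == 1L) cfg$widths[1] else cfg$widths[l - 1L]
    # residual at the small scale, then stride-2 transposed conv (k = 4)
    cinl <- cfg$widths[l]
    p[[sprintf("dec%d_res1_W", l)]] <- init_weight(27L * cinl, cinl)
    p[[sprintf("dec%d_res1_b", l)]] <- numeric(cinl)
    p[[sprintf("dec%d_up_V", l)]] <- init_weight(64L * cout, cinl, gain = 1)
    p[[sprintf("dec%d_up_b", l)]] <- numeric(cout)
  }
  chead <- if (cfg$levels > 0) cfg$widths[1] else 1L
  p[["dec_head_W"]] <- init_weight(chead, 1L, gain = 1)
  p[["dec_head_b"]] <- numeric(1L)
  p
}

vq_encode_forward <- function(x, params, cfg) {
  caches <- list()
  h <- x
  for (l in seq_len(cfg$levels)) {
    cv <- conv3d_forward(h, params[[sprintf("enc%d_down_W", l)]],
                         params[[sprintf("enc%d_down_b", l)]], 3L, 2L, 1L)
    a <- relu(cv$out)
    r1 <- conv3d_forward(a, params[[sprintf("enc%d_res1_W", l)]],
                         params[[sprintf("enc%d_res1_b", l)]], 3L, 1L, 1L)
    a1 <- relu(r1$out)
    r2 <- conv3d_forward(a1, params[[sprintf("enc%d_res2_W", l)]],
                         params[[sprintf("enc%d_res2_b", l)]], 3L, 1L, 1L)
    pre <- a + r2$out
    h2 <- relu(pre)
    caches[[l]] <- list(cv = cv, a = a, r1 = r1, a1 = a1, r2 = r2, pre = pre)
    h <- h2
  }
  d <- dim(h)
  hM <- matrix(h, ncol = d[4])
  zM <- sweep(hM %*% params$enc_proj_W, 2, params$enc_proj_b, `+`)
  ze <- array(zM, dim = c(d[1:3], cfg$n))
  list(ze = ze, caches = caches, hM = hM, h_dim = d)
}

vq_encode_backward <- function(dze, fwd, params, cfg) {
  g <- list()
  d <- fwd$h_dim
  dzM <- matrix(dze, ncol = cfg$n)
  g$enc_proj_W <- crossprod(fwd$hM, dzM)
  g$enc_proj_b <- colSums(dzM)
  dh <- array(dzM %*% t(params$enc_proj_W), dim = d)
  for (l in rev(seq_len(cfg$levels))) {
    cc <- fwd$caches[[l]]
    dpre <- relu_backward(dh, cc$pre)
    b2 <- conv3d_backward(dpre, cc$r2, params[[sprintf("enc%d_res2_W", l)]])
    g[[sprintf("enc%d_res2_W", l)]] <- b2$dW
    g[[sprintf("enc%d_res2_b", l)]] <- b2$db
    da1 <- relu_backward(b2$dx, cc$r1$out)
    b1 <- conv3d_backward(da1, cc$r1, params[[sprintf("enc%d_res1_W", l)]])
    g[[sprintf("enc%d_res1_W", l)]] <- b1$dW
    g[[sprintf("enc%d_res1_b", l)]] <- b1$db
    da <- dpre + b1$dx
    dcv <- relu_backward(da, cc$cv$out)
    bd <- conv3d_backward(dcv, cc$cv, params[[sprintf("enc%d_down_W", l)]],
                          need_dx = l > 1L)
    g[[sprintf("enc%d_down_W", l)]] <- bd$dW
    g[[sprintf("enc%d_down_b", l)]] <- bd$db
    if (l > 1L) dh <- bd$dx
  }
  g
}

vq_decode_forward <- function(zq, params, cfg) {
  d <- dim(zq)
  zM <- matrix(zq, ncol = cfg$n)
  hM <- sweep(zM %*% params$dec_proj_W, 2, params$dec_proj_b, `+`)
  h <- array(hM, dim = c(d[1:3], ncol(hM)))
  hproj_pre <- h
  h <- relu(h)
  caches <- list()
  for (l in rev(seq_len(cfg$levels))) {
    # single-conv residual block at the coarse scale, then upsample
    r1 <- conv3d_forward(h, params[[sprintf("dec%d_res1_W", l)]],
                         params[[sprintf("dec%d_res1_b", l)]], 3L, 1L, 1L)
    res_out <- h + r1$out
    res_act <- relu(res_out)
    up <- deconv3d_forward(res_act, params[[sprintf("dec%d_up_V", l)]],
                           params[[sprintf("dec%d_up_b", l)]], 4L, 2L, 1L,
                           dim(res_act)[1:3] * 2L)
    up_act <- relu(up$out)
    caches[[as.character(l)]] <- list(r1 = r1, res_out = res_out,
                                      res_act = res_act, up = up)
    h <- up_act
  }
  dd <- dim(h)
  hM2 <- matrix(h, ncol = dd[4])
  yM <- sweep(hM2 %*% params$dec_head_W, 2, params$dec_head_b, `+`)
  xhat <- array(yM, dim = dd[1:3])
  list(xhat = xhat, caches = caches, hM2 = hM2, h_dim = dd,
       zM = zM, hproj_pre = hproj_pre)
}

vq_decode_backward <- function(dxhat, fwd, params, cfg) {
  g <- list()
  dd <- fwd$h_dim
  dyM <- matrix(as.vector(dxhat), ncol = 1L)
  g$dec_head_W <- crossprod(fwd$hM2, dyM)
  g$dec_head_b <- sum(dyM)
  dh <- array(dyM %*% t(params$dec_head_W), dim = dd)
  for (l in seq_len(cfg$levels)) {
    cc <- fwd$caches[[as.character(l)]]
    dup_act <- relu_backward(dh, cc$up$out)
    bu <- deconv3d_backward(dup_act, cc$up, params[[sprintf("dec%d_up_V", l)]])
    g[[sprintf("dec%d_up_V", l)]] <- bu$dV
    g[[sprintf("dec%d_up_b", l)]] <- bu$db
    dres_act <- bu$dx
    dres_out <- relu_backward(dres_act, cc$res_out)
    b1 <- conv3d_backward(dres_out, cc$r1, params[[sprintf("dec%d_res1_W", l)]])
    g[[sprintf("dec%d_res1_W", l)]] <- b1$dW
    g[[sprintf("dec%d_res1_b", l)]] <- b1$db
    dh <- dres_out + b1$dx
  }
  dh <- relu_backward(dh, fwd$hproj_pre)
  dhM <- matrix(dh, ncol = dim(dh)[4])
  g$dec_proj_W <- crossprod(fwd$zM, dhM)
  g$dec_proj_b <- colSums(dhM)
  dzq <- array(dhM %*% t(params$dec_proj_W), dim = c(dd[1:3] %/% (2L^cfg$levels), cfg$n))
  list(grads = g, dzq = dzq)
}
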