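# Minimal neural-network core on base-R arrays. Convolutions are im2col
# gathers followed by BLAS matrix multiplies; gradients are hand-derived and
# verified against finite differences in the test suite. Tensors are arrays
# with dims (X, Y, Z, C); weights are matrices (k^3 * Cin) x Cout laid out
# column-major over (kx, ky, kz, c).

.conv_cache <- new.env(parent = emptyenv())

conv3d_prep <- function(spatial, cin, k, stride, pad) {
  key <- paste(c(spatial, cin, k, stride, pad), collapse = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- spatial + 2L * pad
  out <- (spatial + 2L * pad - k) %/% stride + 1L
  ox <- seq_len(out[1]); oy <- seq_len(out[2]); oz <- seq_len(out[3])
  # 0-based base offsets of each output position, x fastest (R array order)
  rb <- rep((ox - 1L) * stride, times = out[2] * out[3])
  cb <- rep(rep((oy - 1L) * stride, each = out[1]), times = out[3])
  db <- rep((oz - 1L) * stride, each = out[1] * out[2])
  rowterm <- rb + cb * P[1] + db * P[1] * P[2]
  kk <- seq_len(k)
  kx <- rep(kk, times = k * k * cin)
  ky <- rep(rep(kk, each = k), times = k * cin)
  kz <- rep(rep(kk, each = k * k), times = cin)
  cc <- rep(seq_len(cin), each = k * k * k)
  colterm <- kx + (ky - 1L) * P[1] + (kz - 1L) * P[1] * P[2] +
    (cc - 1L) * P[1] * P[2] * P[3]
  idx <- outer(as.integer(rowterm), as.integer(colterm), `+`)
  storage.mode(idx) <- "integer"
  n_padded <- prod(P) * cin
  # adjoint of the gather, for scatter-add (col2im) as one sparse crossprod
  scatter <- Matrix::sparseMatrix(i = seq_along(idx), j = as.vector(idx),
                                  x = 1, dims = c(length(idx), n_padded))
  prep <- list(spatial = spatial, cin = cin, k = k, stride = stride, pad = pad,
               padded = P, out = out, n_out = prod(out),
               idx = idx, scatter = scatter)
  .conv_cache[[key]] <- prep
  prep
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1:3] + 2L * pad, d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

unpad_array <- function(x, pad, spatial) {
  if (pad == 0L) return(x)
  x[pad + seq_len(spatial[1]), pad + seq_len(spatial[2]),
    pad + seq_len(spatial[3]), , drop = FALSE]
}

im2col <- function(xp, prep) {
  out <- xp[prep$idx]
  dim(out) <- dim(prep$idx)
  out
}

# Scatter-add columns of `cols` back into a zeroed padded array: the adjoint
# of the im2col gather, applied as one sparse crossprod.
col2im <- function(cols, prep, cout_channels) {
  dxp <- as.vector(Matrix::crossprod(prep$scatter, as.vector(cols)))
  array(dxp, dim = c(prep$padded, cout_channels))
}

conv3d_forward <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  prep <- conv3d_prep(d[1:3], d[4], k, stride, pad)
  cols <- im2col(pad_array(x, pad), prep)
  y <- cols %*% W
  y <- sweep(y, 2, b, `+`)
  list(out = array(y, dim = c(prep$out, ncol(W))), cols = cols, prep = prep)
}

conv3d_backward <- function(dy, cache, W, need_dx = TRUE) {
  prep <- cache$prep
  dyM <- matrix(dy, nrow = prep$n_out)
  dW <- crossprod(cache$cols, dyM)
  db <- colSums(dyM)
  dx <- NULL
  if (need_dx) {
    dcols <- dyM %*% t(W)
    dxp <- col2im(dcols, prep, prep$cin)
    dx <- unpad_array(dxp, prep$pad, prep$spatial)
  }
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution (stride-2 upsampling). Weight V has shape
# (k^3 * Cout) x Cin: the weight of the adjoint convolution mapping the large
# grid back to the small one. forward() is that convolution's input-gradient.
deconv3d_forward <- function(x, V, b, k, stride, pad, out_spatial) {
  d <- dim(x)
  cout <- nrow(V) / k^3
  prep <- conv3d_prep(out_spatial, as.integer(cout), k, stride, pad)
  stopifnot(all(prep$out == d[1:3]))
  xM <- matrix(x, nrow = prep$n_out)
  dcols <- xM %*% t(V)
  yp <- col2im(dcols, prep, as.integer(cout))
  y <- unpad_array(yp, pad, out_spatial)
  y <- sweep(y, 4, b, `+`)
  list(out = y, xM = xM, prep = prep)
}

deconv3d_backward <- function(dy, cache, V) {
  prep <- cache$prep
  cols <- im2col(pad_array(dy, prep$pad), prep)
  dxM <- cols %*% V
  dV <- crossprod(cols, cache$xM)
  db <- apply(dy, 4, sum)
  list(dx = array(dxM, dim = c(prep$out, ncol(V))), dV = dV, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dy, x) {
  dy[x <= 0] <- 0
  dy
}

lrelu <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)

lrelu_backward <- function(dy, x, alpha = 0.2) ifelse(x > 0, dy, alpha * dy)

sigmoid <- function(x) 1 / (1 + exp(-x))

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# He-scaled Gaussian initialisation for a fan_in x fan_out weight matrix.
init_weight <- function(fan_in, fan_out, gain = 2) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(gain / fan_in)), fan_in, fan_out)
}

# --- Adam optimiser over an arbitrary named list of numeric arrays ---------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

accum_grads <- function(acc, g) {
  for (nm in names(g)) {
    if (is.null(g[[nm]])) next
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

scale_grads <- function(g, s) lapply(g, function(x) if (is.null(x)) NULL else x * s)
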