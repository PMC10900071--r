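# Causal transformer over flattened code sequences. Exact (quadratic) causal
# self-attention with learned absolute positional embeddings; pre-LayerNorm
# blocks; a begin-of-sequence token so the first position has a well-defined
# conditional; natural-log likelihoods throughout. Backpropagation is written
# by hand and checked against finite differences in the tests.

#' Flatten a code grid to a token sequence
#'
#' Fixed raster order: axis 1 slowest, the last axis fastest, so grid cell
#' (i, j, k) of an h x w x d grid lands at position (i-1)*w*d + (j-1)*d + k.
#' Likelihoods are order-dependent, so the order is part of the model
#' artefact and is the same everywhere in the package.
#'
#' @param cg a `code_grid` (or a bare integer array of 0-based indices, in
#'   which case `vocab` must be given).
#' @param vocab codebook size `K` when `cg` is a bare array.
#' @return A `token_sequence`: list with `tokens` (0-based integers),
#'   `latent_shape`, `vocab`.
#' @export
flatten_codes <- function(cg, vocab = NULL) {
  if (inherits(cg, "code_grid")) {
    arr <- cg$indices
    vocab <- cg$K
  } else {
    arr <- cg
    abort_if(is.null(vocab), "vocab (K) is required for a bare index array")
  }
  structure(list(tokens = as.integer(raster_flatten(arr)),
                 latent_shape = dim(arr), vocab = as.integer(vocab)),
            class = "token_sequence")
}

#' Restore a token sequence to its code grid
#'
#' Inverse of [flatten_codes()]: `unflatten_codes(flatten_codes(cg))`
#' reproduces the grid exactly.
#'
#' @param ts a `token_sequence`.
#' @param entries optional codebook entries to attach to the rebuilt grid.
#' @return A `code_grid`.
#' @export
unflatten_codes <- function(ts, entries = NULL) {
  abort_if(length(ts$tokens) != prod(ts$latent_shape),
           "token count does not match latent_shape")
  arr <- raster_unflatten(ts$tokens, ts$latent_shape)
  storage.mode(arr) <- "integer"
  new_code_grid(arr, ts$vocab, entries)
}

#' Configure the autoregressive sequence model
#'
#' @param n_layers number of transformer blocks.
#' @param n_heads attention heads (`d_model` must be divisible by it).
#' @param d_model model width.
#' @param mlp_mult width multiplier of the feed-forward stage.
#' @param lr,epochs,batch_size Adam learning rate and schedule.
#' @param seed seed for initialisation and shuffling; training is
#'   deterministic given the seed.
#' @return An object of class `ar_config`.
#' @export
ar_config <- function(n_layers = 4L, n_heads = 4L, d_model = 128L,
                      mlp_mult = 4L, lr = 1e-3, epochs = 10L,
                      batch_size = 8L, seed = 1L) {
  abort_if(d_model %% n_heads != 0, "d_model must be divisible by n_heads")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), mlp_mult = as.integer(mlp_mult),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "ar_config")
}

ar_init_params <- function(cfg, vocab, seq_len) {
  d <- cfg$d_model
  p <- list(
    tok_emb = matrix(stats::rnorm((vocab + 1L) * d, sd = 0.02), vocab + 1L, d),
    pos_emb = matrix(stats::rnorm(seq_len * d, sd = 0.02), seq_len, d)
  )
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d_", l)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- rep(0, d)
    p[[paste0(pre, "Wqkv")]] <- init_weight(d, 3L * d, gain = 1)
    p[[paste0(pre, "bqkv")]] <- numeric(3L * d)
    p[[paste0(pre, "Wo")]] <- init_weight(d, d, gain = 1) / sqrt(2 * cfg$n_layers)
    p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    p[[paste0(pre, "W1")]] <- init_weight(d, cfg$mlp_mult * d)
    p[[paste0(pre, "b1")]] <- numeric(cfg$mlp_mult * d)
    p[[paste0(pre, "W2")]] <- init_weight(cfg$mlp_mult * d, d, gain = 1) / sqrt(2 * cfg$n_layers)
    p[[paste0(pre, "b2")]] <- numeric(d)
  }
  p[["lnf_g"]] <- rep(1, d)
  p[["lnf_b"]] <- rep(0, d)
  p[["Wout"]] <- init_weight(d, vocab, gain = 1)
  p[["bout"]] <- numeric(vocab)
  p
}

LN_EPS <- 1e-5

layernorm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xn <- xc * inv
  list(out = sweep(xn, 2, g, `*`) + rep(b, each = nrow(x)),
       xn = xn, inv = inv)
}

layernorm_backward <- function(dy, cache, g) {
  xn <- cache$xn
  inv <- cache$inv
  dg <- colSums(dy * xn)
  db <- colSums(dy)
  dxn <- sweep(dy, 2, g, `*`)
  d <- ncol(xn)
  dx <- inv * (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn))
  list(dx = dx, dg = dg, db = db)
}

attention_forward <- function(x, p, pre, cfg, mask_neg) {
  ln <- layernorm_forward(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
  qkv <- sweep(ln$out %*% p[[paste0(pre, "Wqkv")]], 2, p[[paste0(pre, "bqkv")]], `+`)
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  Tn <- nrow(x)
  O <- matrix(0, Tn, d)
  heads <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Q <- qkv[, cols, drop = FALSE]
    K <- qkv[, d + cols, drop = FALSE]
    V <- qkv[, 2L * d + cols, drop = FALSE]
    S <- (Q %*% t(K)) / sqrt(dh) + mask_neg
    A <- softmax_rows(S)
    O[, cols] <- A %*% V
    heads[[h]] <- list(Q = Q, K = K, V = V, A = A)
  }
  out <- sweep(O %*% p[[paste0(pre, "Wo")]], 2, p[[paste0(pre, "bo")]], `+`)
  list(out = out, ln = ln, qkv = qkv, O = O, heads = heads)
}

attention_backward <- function(dy, cache, p, pre, cfg) {
  g <- list()
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  g[[paste0(pre, "Wo")]] <- crossprod(cache$O, dy)
  g[[paste0(pre, "bo")]] <- colSums(dy)
  dO <- dy %*% t(p[[paste0(pre, "Wo")]])
  dqkv <- matrix(0, nrow(dy), 3L * d)
  for (h in seq_len(nh)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    hd <- cache$heads[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(hd$V)
    dV <- crossprod(hd$A, dOh)
    dS <- (dA - rowSums(dA * hd$A)) * hd$A
    dQ <- (dS %*% hd$K) / sqrt(dh)
    dK <- (crossprod(dS, hd$Q)) / sqrt(dh)
    dqkv[, cols] <- dQ
    dqkv[, d + cols] <- dK
    dqkv[, 2L * d + cols] <- dV
  }
  g[[paste0(pre, "Wqkv")]] <- crossprod(cache$ln$out, dqkv)
  g[[paste0(pre, "bqkv")]] <- colSums(dqkv)
  dln_out <- dqkv %*% t(p[[paste0(pre, "Wqkv")]])
  lb <- layernorm_backward(dln_out, cache$ln, p[[paste0(pre, "ln1_g")]])
  g[[paste0(pre, "ln1_g")]] <- lb$dg
  g[[paste0(pre, "ln1_b")]] <- lb$db
  list(dx = lb$dx, grads = g)
}

mlp_forward <- function(x, p, pre) {
  ln <- layernorm_forward(x, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
  h1 <- sweep(ln$out %*% p[[paste0(pre, "W1")]], 2, p[[paste0(pre, "b1")]], `+`)
  a1 <- relu(h1)
  out <- sweep(a1 %*% p[[paste0(pre, "W2")]], 2, p[[paste0(pre, "b2")]], `+`)
  list(out = out, ln = ln, h1 = h1, a1 = a1)
}

mlp_backward <- function(dy, cache, p, pre) {
  g <- list()
  g[[paste0(pre, "W2")]] <- crossprod(cache$a1, dy)
  g[[paste0(pre, "b2")]] <- colSums(dy)
  da1 <- dy %*% t(p[[paste0(pre, "W2")]])
  dh1 <- relu_backward(da1, cache$h1)
  g[[paste0(pre, "W1")]] <- crossprod(cache$ln$out, dh1)
  g[[paste0(pre, "b1")]] <- colSums(dh1)
  dln_out <- dh1 %*% t(p[[paste0(pre, "W1")]])
  lb <- layernorm_backward(dln_out, cache$ln, p[[paste0(pre, "ln2_g")]])
  g[[paste0(pre, "ln2_g")]] <- lb$dg
  g[[paste0(pre, "ln2_b")]] <- lb$db
  list(dx = lb$dx, grads = g)
}

# Forward pass for one sequence of 0-based tokens; returns logits (T x K) and
# caches for backprop. Input at position t is the embedding of token t-1
# (BOS at t = 1) plus the positional embedding.
ar_forward <- function(tokens, params, cfg, vocab, mask_neg, want_cache = TRUE) {
  Tn <- length(tokens)
  ids <- c(vocab, tokens[-Tn]) + 1L # BOS id = vocab (0-based), 1-based rows
  x <- params$tok_emb[ids, , drop = FALSE] + params$pos_emb[seq_len(Tn), , drop = FALSE]
  caches <- if (want_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d_", l)
    att <- attention_forward(x, params, pre, cfg, mask_neg)
    x1 <- x + att$out
    mlp <- mlp_forward(x1, params, pre)
    x2 <- x1 + mlp$out
    if (want_cache) caches[[l]] <- list(att = att, mlp = mlp)
    x <- x2
  }
  lnf <- layernorm_forward(x, params$lnf_g, params$lnf_b)
  logits <- sweep(lnf$out %*% params$Wout, 2, params$bout, `+`)
  list(logits = logits, caches = caches, lnf = lnf, ids = ids, Tn = Tn)
}

ar_backward <- function(dlogits, fwd, params, cfg) {
  g <- list()
  g$Wout <- crossprod(fwd$lnf$out, dlogits)
  g$bout <- colSums(dlogits)
  dlnf_out <- dlogits %*% t(params$Wout)
  lb <- layernorm_backward(dlnf_out, fwd$lnf, params$lnf_g)
  g$lnf_g <- lb$dg
  g$lnf_b <- lb$db
  dx <- lb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("l%d_", l)
    cc <- fwd$caches[[l]]
    mb <- mlp_backward(dx, cc$mlp, params, pre)
    g <- accum_grads(g, mb$grads)
    dx <- dx + mb$dx
    ab <- attention_backward(dx, cc$att, params, pre, cfg)
    g <- accum_grads(g, ab$grads)
    dx <- dx + ab$dx
  }
  # embedding gradients: scatter rows by input id, add positional directly
  demb <- matrix(0, nrow(params$tok_emb), ncol(params$tok_emb))
  agg <- rowsum(dx, group = fwd$ids)
  demb[as.integer(rownames(agg)), ] <- agg
  g$tok_emb <- demb
  g$pos_emb <- dx
  g
}

causal_mask_neg <- function(Tn) {
  m <- matrix(0, Tn, Tn)
  m[upper.tri(m)] <- -Inf
  m
}

#' Train the autoregressive model on token sequences
#'
#' Minimises the cross-entropy of next-token prediction (equivalently,
#' maximises the log-likelihood of the training sequences) with Adam.
#' Sequences must share their vocabulary and length. Deterministic given
#' `cfg$seed`.
#'
#' @param sequences list of `token_sequence` objects.
#' @param cfg an [ar_config()].
#' @param verbose print per-epoch mean negative log-likelihood per token.
#' @return An `ar_model`: list with `params`, `cfg`, `vocab`, `seq_len`,
#'   `latent_shape`, and `curve` (tibble of per-epoch mean NLL per token,
#'   in nats).
#' @export
train_ar <- function(sequences, cfg = ar_config(), verbose = FALSE) {
  abort_if(length(sequences) == 0, "sequences must be non-empty")
  vocab <- sequences[[1]]$vocab
  seq_len_ <- length(sequences[[1]]$tokens)
  latent_shape_ <- sequences[[1]]$latent_shape
  for (s in sequences) {
    abort_if(s$vocab != vocab || length(s$tokens) != seq_len_,
             "all sequences must share vocab and length")
    abort_if(any(s$tokens < 0L) || any(s$tokens >= vocab),
             "tokens must lie in [0, vocab)")
  }
  toks <- lapply(sequences, function(s) s$tokens)
  set.seed(cfg$seed)
  params <- ar_init_params(cfg, vocab, seq_len_)
  opt <- adam_init(params)
  mask_neg <- causal_mask_neg(seq_len_)
  n <- length(toks)
  curve <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_nll <- 0
    for (batch in batches) {
      acc <- list()
      for (i in batch) {
        tk <- toks[[i]]
        fwd <- ar_forward(tk, params, cfg, vocab, mask_neg)
        P <- softmax_rows(fwd$logits)
        tgt_idx <- cbind(seq_len(seq_len_), tk + 1L)
        nll <- -mean(log(pmax(P[tgt_idx], 1e-300)))
        ep_nll <- ep_nll + nll
        dlogits <- P
        dlogits[tgt_idx] <- dlogits[tgt_idx] - 1
        dlogits <- dlogits / seq_len_
        acc <- accum_grads(acc, ar_backward(dlogits, fwd, params, cfg))
      }
      acc <- scale_grads(acc, 1 / length(batch))
      st <- adam_step(params, acc, opt, lr = cfg$lr)
      params <- st$params; opt <- st$state
    }
    curve[epoch] <- ep_nll / n
    if (verbose) message(sprintf("epoch %d: nll/token %.4f", epoch, curve[epoch]))
  }

  structure(
    list(params = params, cfg = cfg, vocab = vocab, seq_len = seq_len_,
         latent_shape = latent_shape_,
         curve = tibble::tibble(epoch = seq_len(cfg$epochs), nll_per_token = curve)),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> %d layers, %d heads, width %d; vocab %d, seq_len %d\n",
              x$cfg$n_layers, x$cfg$n_heads, x$cfg$d_model, x$vocab, x$seq_len))
  if (nrow(x$curve)) {
    cat(sprintf("  final nll/token: %.4f nats\n",
                x$curve$nll_per_token[nrow(x$curve)]))
  }
  invisible(x)
}

#' Full conditional distributions along a sequence
#'
#' @param model an `ar_model`.
#' @param ts a `token_sequence` of the model's trained length.
#' @return A `seq_len x vocab` matrix; row i is the model's conditional
#'   distribution of token i given tokens before i (each row sums to 1).
#' @export
ar_conditionals <- function(model, ts) {
  abort_if(length(ts$tokens) != model$seq_len,
           "sequence length does not match the trained model")
  abort_if(any(ts$tokens < 0L) || any(ts$tokens >= model$vocab),
           "token outside the model's vocabulary")
  fwd <- ar_forward(ts$tokens, model$params, model$cfg, model$vocab,
                    causal_mask_neg(model$seq_len), want_cache = FALSE)
  softmax_rows(fwd$logits)
}

#' Exact sequence log-likelihood
#'
#' The autoregressive factorisation log p(s) = sum_i log p(s_i | s_<i),
#' evaluated exactly in one forward pass (nats).
#'
#' @param ts a `token_sequence`.
#' @param model an `ar_model` trained at the same length and vocabulary.
#' @return A `likelihood_result`: list with `total_loglik`, `per_token_logp`
#'   and `latent_shape`.
#' @export
sequence_loglik <- function(ts, model) {
  P <- ar_conditionals(model, ts)
  lp <- log(pmax(P[cbind(seq_len(model$seq_len), ts$tokens + 1L)], 1e-300))
  structure(list(total_loglik = sum(lp), per_token_logp = lp,
                 latent_shape = ts$latent_shape),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("<likelihood_result> total log-lik %.2f nats over %d tokens\n",
              x$total_loglik, length(x$per_token_logp)))
  invisible(x)
}

#' Spatial likelihood map
#'
#' Per-token conditional log-probabilities reshaped back to the latent grid
#' (inverting the raster order) and nearest-neighbour upsampled by an integer
#' factor along each axis, so low-likelihood regions can be localised at
#' image resolution.
#'
#' @param lr a `likelihood_result`.
#' @param upsample_factor integer >= 1 (use `2^levels` to match the encoder).
#' @return A numeric array of shape `latent_shape * upsample_factor`.
#' @export
spatial_likelihood_map <- function(lr, upsample_factor = 1L) {
  abort_if(!is_scalar_number(upsample_factor) || upsample_factor < 1,
           "upsample_factor must be an integer >= 1")
  abort_if(length(lr$per_token_logp) != prod(lr$latent_shape),
           "likelihood result inconsistent with its latent_shape")
  grid <- raster_unflatten(lr$per_token_logp, lr$latent_shape)
  nn_upsample(grid, as.integer(upsample_factor))
}
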