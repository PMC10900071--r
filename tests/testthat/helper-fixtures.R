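# Shared fixtures. Small phantom families keep unit tests fast; the scaled
# end-to-end experiment is trained once per session and memoised.

small_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(16L, 16L, 16L), seed = seed, ...)
}

make_token_seq <- function(tokens, vocab, latent_shape = c(1L, 1L, length(tokens))) {
  structure(list(tokens = as.integer(tokens), latent_shape = latent_shape,
                 vocab = as.integer(vocab)),
            class = "token_sequence")
}

# A model wrapper around raw parameters, for closed-form likelihood tests.
make_ar_model <- function(params, cfg, vocab, seq_len) {
  structure(list(params = params, cfg = cfg, vocab = vocab, seq_len = seq_len,
                 latent_shape = c(1L, 1L, seq_len),
                 curve = tibble::tibble(epoch = integer(), nll_per_token = numeric())),
            class = "ar_model")
}

# An untrained autoencoder (seeded random weights) for shape/finiteness tests.
untrained_vq <- function(input_shape, cfg = vq_config(seed = 11L)) {
  set.seed(cfg$seed)
  structure(
    list(cfg = cfg, params = ltmood:::vq_init_params(cfg),
         codebook = new_codebook(cfg$K, cfg$n, seed = cfg$seed),
         input_shape = input_shape, ls = latent_shape(input_shape, cfg$levels),
         curve = tibble::tibble(), disc = NULL),
    class = "vq_model"
  )
}

# The scaled OOD experiment (the acceptance workhorse): trained once, shared
# by every test that needs a fitted pipeline.
.exp_cache <- new.env(parent = emptyenv())

scaled_experiment <- function() {
  if (is.null(.exp_cache$exp)) {
    .exp_cache$exp <- ood_experiment(n_train = 200L, n_test = 20L, seed = 1L)
  }
  .exp_cache$exp
}
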