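# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

#' Derive a child seed from a base seed and an index
#'
#' Deterministic integer arithmetic kept strictly below 2^31 so results are
#' valid R integer seeds on every platform.
#'
#' @param base integer base seed.
#' @param i non-negative integer index.
#' @return An integer seed.
#' @export
derive_seed <- function(base, i) {
  m <- 2147483629 # largest prime < 2^31
  as.integer((as.numeric(base) %% m * 48271 + as.numeric(i) * 7919 + 12345) %% m)
}

# Stable 31-bit hash of a character string (used to derive per-corruption
# noise seeds from source id + parameters without a digest dependency).
string_seed <- function(s) {
  v <- utf8ToInt(s)
  h <- 5381
  m <- 2147483629
  for (ch in v) h <- (h * 33 + ch) %% m
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Flatten order used everywhere tokens meet grids: axis 1 slowest, axis 3
# fastest, i.e. grid cell (i, j, k) maps to position
# (i-1)*W*D + (j-1)*D + k in the 1D sequence.
raster_flatten <- function(arr) {
  as.vector(aperm(arr, rev(seq_along(dim(arr)))))
}

raster_unflatten <- function(v, shape) {
  aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}

# Nearest-neighbour upsampling of an array by an integer factor per axis.
nn_upsample <- function(arr, factor) {
  d <- dim(arr)
  idx <- lapply(d, function(n) rep(seq_len(n), each = factor))
  do.call(`[`, c(list(arr), idx))
}
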