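# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.ar_model
#' @export
tidy.vq_model <- function(x, ...) x$curve

#' @export
glance.vq_model <- function(x, ...) {
  trained <- nrow(x$curve) > 0
  tibble::tibble(
    levels = x$cfg$levels, K = x$cfg$K, n = x$cfg$n,
    epochs = nrow(x$curve),
    final_mse = if (trained) x$curve$mse[nrow(x$curve)] else NA_real_,
    final_total = if (trained) x$curve$total[nrow(x$curve)] else NA_real_,
    codes_active = sum(x$codebook$ema_counts > 1e-3 * sum(x$codebook$ema_counts) / x$cfg$K),
    sequence_length = x$ls$sequence_length
  )
}

#' Tidy training curves and fits
#'
#' `tidy()` on a `vq_model` or `ar_model` returns the per-epoch training
#' curve; on a `likelihood_result` the per-token conditionals; on an
#' `ood_experiment` the per-class summary. `glance()` returns one-row model
#' summaries.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ar_model <- function(x, ...) x$curve

#' @export
glance.ar_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$cfg$n_layers, n_heads = x$cfg$n_heads,
    d_model = x$cfg$d_model, vocab = x$vocab, seq_len = x$seq_len,
    epochs = nrow(x$curve),
    final_nll_per_token = x$curve$nll_per_token[nrow(x$curve)]
  )
}

#' @rdname tidy.ar_model
#' @export
tidy.likelihood_result <- function(x, ...) {
  tibble::tibble(position = seq_along(x$per_token_logp),
                 logp = x$per_token_logp)
}

#' @rdname tidy.ar_model
#' @export
tidy.ood_experiment <- function(x, ...) x$summary

#' @export
glance.ood_experiment <- function(x, ...) {
  aucs <- x$summary$auc[x$summary$group_label != "in_distribution"]
  tibble::tibble(
    n_train = x$n_train, n_test = x$n_test,
    n_classes = length(x$suite),
    min_auc = min(aucs), median_auc = stats::median(aucs), max_auc = max(aucs),
    runtime_s = x$runtime_s
  )
}
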