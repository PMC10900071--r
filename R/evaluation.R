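# Score-based OOD evaluation: Mann-Whitney AUC, threshold policies, per-class
# summaries and the likelihood-versus-false-positive analysis. Score tables
# are plain tibbles with columns (volume_id, group_label, score_name,
# score_value); the in-distribution group is labelled "in_distribution".

#' Build a score table
#'
#' @param volume_id,group_label,score_name,score_value equal-length vectors.
#' @return A validated `score_table` tibble.
#' @export
score_table <- function(volume_id, group_label, score_name, score_value) {
  tb <- tibble::tibble(volume_id = as.character(volume_id),
                       group_label = as.character(group_label),
                       score_name = as.character(score_name),
                       score_value = as.numeric(score_value))
  validate_score_table(tb)
  tb
}

validate_score_table <- function(tb) {
  need <- c("volume_id", "group_label", "score_name", "score_value")
  abort_if(!all(need %in% names(tb)),
           "score table needs volume_id, group_label, score_name, score_value")
  dup <- duplicated(tb[, c("volume_id", "score_name")])
  abort_if(any(dup), "duplicate (volume_id, score_name) pairs in score table")
  invisible(tb)
}

#' Area under the ROC curve for OOD separation
#'
#' The Mann-Whitney construction: the probability that a random
#' (in-distribution, OOD) pair is ordered correctly under the declared score
#' direction, with ties counting one half. Computed from average ranks, which
#' is exactly the pairwise count with half-ties.
#'
#' @param in_scores scores of in-distribution items.
#' @param ood_scores scores of OOD items.
#' @param direction `"low_is_ood"` for log-likelihoods (OOD scores are
#'   expected to be lower), `"high_is_ood"` for reconstruction error.
#' @return AUC in \[0, 1\]; 1 means perfect separation, 0.5 chance.
#' @export
ood_auc <- function(in_scores, ood_scores,
                    direction = c("low_is_ood", "high_is_ood")) {
  direction <- match.arg(direction)
  abort_if(length(in_scores) == 0 || length(ood_scores) == 0,
           "both score lists must be non-empty")
  abort_if(!all(is.finite(c(in_scores, ood_scores))), "scores must be finite")
  x <- if (direction == "low_is_ood") in_scores else -in_scores
  y <- if (direction == "low_is_ood") ood_scores else -ood_scores
  r <- rank(c(x, y))
  n_in <- length(x); n_ood <- length(y)
  (sum(r[seq_len(n_in)]) - n_in * (n_in + 1) / 2) / (n_in * n_ood)
}

#' Threshold policy for flagging OOD volumes
#'
#' @param kind `"absolute"` (flag when log-likelihood < `value`) or
#'   `"training_percentile"` (threshold at the given percentile of the
#'   training log-likelihoods, `value` in (0, 100)).
#' @param value the threshold or percentile.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(kind = c("absolute", "training_percentile"),
                             value) {
  kind <- match.arg(kind)
  abort_if(!is_scalar_number(value), "value must be a finite scalar")
  if (kind == "training_percentile") {
    abort_if(value <= 0 || value >= 100, "percentile must lie in (0, 100)")
  }
  structure(list(kind = kind, value = value), class = "threshold_policy")
}

#' Flag OOD volumes by a one-sided likelihood threshold
#'
#' A volume is flagged OOD iff its log-likelihood is strictly lower than the
#' threshold; the threshold is `policy$value` itself (absolute) or that
#' percentile of the training log-likelihoods (type-1 empirical quantile, so
#' the 1st percentile of 100 training scores is exactly the lowest one).
#'
#' @param scores a `score_table` (or tibble with `volume_id`, `score_value`).
#' @param policy a [threshold_policy()].
#' @param training_scores numeric training log-likelihoods (required for the
#'   percentile policy).
#' @return The tibble with `threshold` and logical `flag_ood` columns added.
#' @export
ood_decision <- function(scores, policy, training_scores = NULL) {
  abort_if(!inherits(policy, "threshold_policy"), "policy must be a threshold_policy")
  thr <- if (policy$kind == "absolute") {
    policy$value
  } else {
    abort_if(is.null(training_scores),
             "training_scores are required for the percentile policy")
    stats::quantile(training_scores, policy$value / 100, type = 1, names = FALSE)
  }
  dplyr::mutate(scores, threshold = thr, flag_ood = .data$score_value < thr)
}

#' Per-class summary of a score table
#'
#' One row per group: mean and sd of the score, and the AUC of that group
#' against the in-distribution group (NA for the in-distribution row itself).
#'
#' @param scores a `score_table`.
#' @param score_name which score to summarise (default the first present).
#' @param direction score direction passed to [ood_auc()].
#' @param in_label the in-distribution group label.
#' @return A tibble with `group_label`, `n`, `mean`, `sd`, `auc`.
#' @export
summarise_by_class <- function(scores, score_name = NULL,
                               direction = "low_is_ood",
                               in_label = "in_distribution") {
  validate_score_table(scores)
  score_name <- score_name %||% scores$score_name[1]
  tb <- dplyr::filter(scores, .data$score_name == !!score_name)
  abort_if(!in_label %in% tb$group_label,
           sprintf("no '%s' group present", in_label))
  in_scores <- tb$score_value[tb$group_label == in_label]
  tb |>
    dplyr::group_by(.data$group_label) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$score_value),
                     sd = stats::sd(.data$score_value),
                     .groups = "drop") |>
    dplyr::mutate(auc = purrr::map_dbl(.data$group_label, function(gl) {
      if (gl == in_label) return(NA_real_)
      ood_auc(in_scores, tb$score_value[tb$group_label == gl], direction)
    })) |>
    dplyr::arrange(.data$group_label != in_label, .data$group_label)
}

#' Join image likelihoods with segmentation false-positive counts
#'
#' The filtering analysis: how strongly does the image log-likelihood predict
#' the segmentation network's failure (FP lesion count)? Reported with a
#' Spearman rank correlation (the relation is monotone, not linear).
#'
#' @param scores a `score_table` holding log-likelihood scores.
#' @param fp_counts tibble with `volume_id`, `fp_count`.
#' @param score_name which score column to use.
#' @return A list with `table` (joined tibble) and `spearman_rho` (NA with a
#'   warning when either side is constant).
#' @export
likelihood_vs_fp <- function(scores, fp_counts, score_name = "loglik") {
  validate_score_table(scores)
  tb <- dplyr::filter(scores, .data$score_name == !!score_name)
  missing_ids <- union(setdiff(tb$volume_id, fp_counts$volume_id),
                       setdiff(fp_counts$volume_id, tb$volume_id))
  abort_if(length(missing_ids) > 0,
           paste("volume_id mismatch:", paste(missing_ids, collapse = ", ")))
  joined <- dplyr::inner_join(
    dplyr::select(tb, "volume_id", loglik = "score_value"),
    fp_counts, by = "volume_id"
  )
  rho <- if (stats::sd(joined$fp_count) == 0 || stats::sd(joined$loglik) == 0) {
    warning("constant scores or FP counts; rank correlation undefined")
    NA_real_
  } else {
    stats::cor(joined$loglik, joined$fp_count, method = "spearman")
  }
  list(table = joined, spearman_rho = rho)
}
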