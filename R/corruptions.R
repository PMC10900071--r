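# Near-OOD corruption suite. Each corruption takes a preprocessed volume
# (intensities in [0,1], background exactly 0) and returns a corrupted copy,
# co-transforming masks where the geometry changes (flips). The default suite
# mirrors the corrupted-CT benchmark classes: additive Gaussian noise at three
# levels, background substitution at three values, flips through the three
# central planes, slice-chunk deletion (central / upper), mask-based skull
# stripping, and global intensity scaling by 0.1 or 0.01.

CORRUPTION_KINDS <- c("noise", "background_value", "flip", "chunk_delete",
                      "skull_strip", "intensity_scale")

# Axis convention: axis 1 = sagittal (L-R), axis 2 = coronal (A-P),
# axis 3 = axial (I-S). Flipping "sagittal" mirrors axis 1, etc.
FLIP_AXES <- c(sagittal = 1L, coronal = 2L, axial = 3L)

#' Specify a corruption
#'
#' @param kind one of `"noise"` (additive zero-mean Gaussian N(0, sd^2),
#'   parameter `sd`), `"background_value"` (replace voxels exactly equal to 0 with
#'   `value`), `"flip"` (mirror through the central `plane`, one of
#'   `"sagittal"`, `"coronal"`, `"axial"`; masks are co-transformed),
#'   `"chunk_delete"` (zero a contiguous block of axial slices covering
#'   `fraction` of the axial extent at `location` `"central"` or `"upper"`),
#'   `"skull_strip"` (zero everything outside the brain mask), or
#'   `"intensity_scale"` (multiply all intensities by `factor`).
#' @param sd,value,plane,location,fraction,factor kind-specific
#'   parameters (see `kind`).
#' @param seed integer seed (noise only); if `NULL`, a seed is derived from
#'   the source volume id and the parameters at application time.
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(kind,
                            sd = NULL, value = NULL, plane = NULL,
                            location = NULL, fraction = 0.2, factor = NULL,
                            seed = NULL) {
  kind <- match.arg(kind, CORRUPTION_KINDS)
  params <- switch(kind,
    noise = {
      abort_if(!is_scalar_number(sd) || sd < 0,
               "noise requires a non-negative sd")
      list(sd = sd)
    },
    background_value = {
      abort_if(!is_scalar_number(value), "background_value requires a value")
      list(value = value)
    },
    flip = {
      plane <- match.arg(plane, names(FLIP_AXES))
      list(plane = plane)
    },
    chunk_delete = {
      location <- match.arg(location, c("central", "upper"))
      abort_if(!is_scalar_number(fraction) || fraction <= 0 || fraction > 1,
               "chunk_delete fraction must lie in (0, 1]")
      list(location = location, fraction = fraction)
    },
    skull_strip = list(),
    intensity_scale = {
      abort_if(!is_scalar_number(factor), "intensity_scale requires a factor")
      list(factor = factor)
    }
  )
  structure(list(kind = kind, params = params, seed = seed),
            class = "corruption_spec")
}

#' @export
print.corruption_spec <- function(x, ...) {
  cat(sprintf("<corruption_spec> %s\n", corruption_label(x)))
  invisible(x)
}

#' Human-readable label for a corruption spec
#'
#' @param spec a `corruption_spec`.
#' @return A string such as `"noise_sd0.1"` or `"flip_sagittal"`.
#' @export
corruption_label <- function(spec) {
  p <- spec$params
  switch(spec$kind,
    noise = sprintf("noise_sd%g", p$sd),
    background_value = sprintf("bg_value%g", p$value),
    flip = sprintf("flip_%s", p$plane),
    chunk_delete = sprintf("chunk_%s", p$location),
    skull_strip = "skull_strip",
    intensity_scale = sprintf("scale_%g", p$factor)
  )
}

#' The default near-OOD corruption suite
#'
#' Fourteen corruptions: Gaussian noise at sd 0.01/0.1/0.2, background values
#' 0.3/0.6/1.0, the three plane flips, central and upper chunk deletion,
#' skull stripping, and intensity scaling by 0.1 and 0.01.
#'
#' @return A list of `corruption_spec` objects, named by [corruption_label()].
#' @export
default_corruption_suite <- function() {
  suite <- c(
    lapply(c(0.01, 0.1, 0.2), function(s) corruption_spec("noise", sd = s)),
    lapply(c(0.3, 0.6, 1.0), function(b) corruption_spec("background_value", value = b)),
    lapply(names(FLIP_AXES), function(p) corruption_spec("flip", plane = p)),
    lapply(c("central", "upper"), function(l) corruption_spec("chunk_delete", location = l)),
    list(corruption_spec("skull_strip")),
    lapply(c(0.1, 0.01), function(f) corruption_spec("intensity_scale", factor = f))
  )
  names(suite) <- vapply(suite, corruption_label, character(1))
  suite
}

flip_array <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Apply a corruption to a volume
#'
#' Masks present on the input are carried over; for flips they are mirrored
#' through the same plane so they stay aligned with the image. Noise is not
#' clamped back to \[0, 1\]: clipping would censor the statistical signature
#' of the stronger noise levels.
#'
#' @param v a `volume`.
#' @param spec a [corruption_spec()].
#' @return A `corrupted_volume`: list with `volume`, `spec`, `source_id`.
#' @export
apply_corruption <- function(v, spec) {
  abort_if(!inherits(spec, "corruption_spec"), "spec must be a corruption_spec")
  abort_if(!all(is.finite(v$intensities)), "volume intensities must be finite")
  img <- v$intensities
  out <- v
  p <- spec$params
  switch(spec$kind,
    noise = {
      seed <- spec$seed %||% string_seed(paste(v$id %||% "vol", "noise", p$sd))
      out$intensities <- with_seed(seed, {
        img + array(stats::rnorm(length(img), sd = p$sd), dim = dim(img))
      })
    },
    background_value = {
      bg <- img == 0
      img[bg] <- p$value
      out$intensities <- img
    },
    flip = {
      ax <- FLIP_AXES[[p$plane]]
      out$intensities <- flip_array(img, ax)
      if (!is.null(v$brain_mask)) out$brain_mask <- flip_array(v$brain_mask, ax)
      if (!is.null(v$lesion_mask)) out$lesion_mask <- flip_array(v$lesion_mask, ax)
    },
    chunk_delete = {
      nz <- dim(img)[3]
      width <- max(1L, as.integer(floor(p$fraction * nz)))
      start <- if (p$location == "central") {
        as.integer(floor((nz - width) / 2)) + 1L
      } else {
        nz - width + 1L
      }
      img[, , start:(start + width - 1L)] <- 0
      out$intensities <- img
    },
    skull_strip = {
      abort_if(is.null(v$brain_mask), "skull_strip requires a brain_mask")
      img[!v$brain_mask] <- 0
      out$intensities <- img
    },
    intensity_scale = {
      out$intensities <- img * p$factor
    }
  )
  structure(list(volume = out, spec = spec, source_id = v$id %||% NA_character_),
            class = "corrupted_volume")
}

#' Corrupt every volume in a cohort with every corruption in a suite
#'
#' @param cohort non-empty list of `volume` objects.
#' @param suite non-empty list of `corruption_spec` objects (e.g.
#'   [default_corruption_suite()]).
#' @param on_error `"fail"` propagates any corruption error; `"skip"` drops
#'   the failing combination with a warning (e.g. skull stripping a volume
#'   that carries no brain mask).
#' @return A list of `corrupted_volume` objects of length
#'   `length(cohort) * length(suite)` (minus skips), cohort-major.
#' @export
corrupt_cohort <- function(cohort, suite = default_corruption_suite(),
                           on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  abort_if(length(cohort) == 0, "cohort must be non-empty")
  abort_if(length(suite) == 0, "suite must be non-empty")
  out <- vector("list", length(cohort) * length(suite))
  k <- 1L
  for (v in cohort) {
    for (spec in suite) {
      cv <- if (on_error == "fail") {
        apply_corruption(v, spec)
      } else {
        tryCatch(apply_corruption(v, spec), error = function(e) {
          warning(sprintf("skipping %s on %s: %s", corruption_label(spec),
                          v$id %||% "volume", conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      }
      if (!is.null(cv)) {
        out[[k]] <- cv
        k <- k + 1L
      }
    }
  }
  out[seq_len(k - 1L)]
}

#' Manifest tibble for a corrupted cohort
#'
#' @param corrupted list of `corrupted_volume` objects.
#' @return A tibble with columns `source_id`, `corruption_kind`,
#'   `corruption_label`, `params_json`, `is_ood`.
#' @export
corruption_manifest <- function(corrupted) {
  tibble::tibble(
    source_id = vapply(corrupted, function(x) x$source_id, character(1)),
    corruption_kind = vapply(corrupted, function(x) x$spec$kind, character(1)),
    corruption_label = vapply(corrupted, function(x) corruption_label(x$spec), character(1)),
    params_json = vapply(corrupted, function(x) {
      as.character(jsonlite::toJSON(x$spec$params, auto_unbox = TRUE))
    }, character(1)),
    is_ood = 1L
  )
}
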