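# Synthetic head phantoms: seeded 3D volumes with skull shell, brain interior,
# smooth tissue texture and optional bright lesions. These stand in for head
# CT preprocessed to [0, 1] with background mapped to exactly 0, and give every
# downstream stage (corruption, compression, likelihood, segmentation) a fully
# reproducible data source.

#' Specify a synthetic head phantom family
#'
#' A phantom is built from two concentric ellipsoids: a bright shell (the
#' "skull"), a mid-intensity interior (the "brain") carrying smooth texture
#' noise, and a background of exactly 0, mirroring CT preprocessing that clamps
#' intensities and rescales to \[0, 1\]. Optional compact bright blobs inside
#' the brain emulate haemorrhagic lesions and come with voxel-exact masks.
#'
#' Default intensities follow the clamp-to-\[-15, 100\]-then-rescale convention
#' for head CT: bone near the top of the range (0.95), brain tissue mid-range
#' (0.4), acute blood brighter than brain (0.75). Texture noise of sd 0.05
#' emulates tissue heterogeneity plus quantum noise of a few Hounsfield units.
#'
#' @param grid_shape integer length-3 vector of voxel dimensions (each >= 8).
#' @param skull_intensity shell intensity in (0, 1]; must exceed
#'   `brain_intensity`.
#' @param brain_intensity interior intensity in (0, 1).
#' @param lesion_count_range integer pair `c(min, max)` of lesions per phantom.
#' @param lesion_intensity lesion intensity in (0, 1].
#' @param texture_noise_sd standard deviation (>= 0) of the smoothed Gaussian
#'   texture added to brain voxels.
#' @param spacing voxel spacing in mm (length 3).
#' @param seed integer seed; phantoms are pure functions of the spec.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
#' @examples
#' spec <- phantom_spec(seed = 1)
#' vol <- generate_phantom(spec)
#' range(vol$intensities)
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         skull_intensity = 0.95,
                         brain_intensity = 0.4,
                         lesion_count_range = c(1L, 2L),
                         lesion_intensity = 0.75,
                         texture_noise_sd = 0.05,
                         spacing = c(1, 1, 1),
                         seed = 1L) {
  spec <- structure(
    list(
      grid_shape = as.integer(grid_shape),
      skull_intensity = skull_intensity,
      brain_intensity = brain_intensity,
      lesion_count_range = as.integer(lesion_count_range),
      lesion_intensity = lesion_intensity,
      texture_noise_sd = texture_noise_sd,
      spacing = as.numeric(spacing),
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  abort_if(length(spec$grid_shape) != 3L || any(spec$grid_shape < 8L),
           "grid_shape must be three integers, each >= 8")
  abort_if(!is_scalar_number(spec$skull_intensity) ||
             spec$skull_intensity <= 0 || spec$skull_intensity > 1,
           "skull_intensity must lie in (0, 1]")
  abort_if(!is_scalar_number(spec$brain_intensity) ||
             spec$brain_intensity <= 0 || spec$brain_intensity >= 1,
           "brain_intensity must lie in (0, 1)")
  abort_if(spec$skull_intensity <= spec$brain_intensity,
           "intensities must be ordered: skull_intensity > brain_intensity > 0")
  abort_if(length(spec$lesion_count_range) != 2L ||
             any(spec$lesion_count_range < 0L) ||
             spec$lesion_count_range[1] > spec$lesion_count_range[2],
           "lesion_count_range must be an ordered non-negative integer pair")
  abort_if(!is_scalar_number(spec$lesion_intensity) ||
             spec$lesion_intensity <= 0 || spec$lesion_intensity > 1,
           "lesion_intensity must lie in (0, 1]")
  abort_if(!is_scalar_number(spec$texture_noise_sd) || spec$texture_noise_sd < 0,
           "texture_noise_sd must be >= 0")
  invisible(spec)
}

#' Construct a volume from an intensity array
#'
#' @param intensities 3D numeric array.
#' @param spacing voxel spacing in mm.
#' @param brain_mask,lesion_mask optional logical arrays of the same shape.
#' @param id optional identifier.
#' @return An object of class `volume`.
#' @export
new_volume <- function(intensities, spacing = c(1, 1, 1),
                       brain_mask = NULL, lesion_mask = NULL, id = NULL) {
  structure(
    list(intensities = intensities, spacing = as.numeric(spacing),
         brain_mask = brain_mask, lesion_mask = lesion_mask, id = id),
    class = "volume"
  )
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume%s> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              paste(d, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  if (!is.null(x$brain_mask)) cat(sprintf("  brain_mask: %d voxels\n", sum(x$brain_mask)))
  if (!is.null(x$lesion_mask)) cat(sprintf("  lesion_mask: %d voxels\n", sum(x$lesion_mask)))
  invisible(x)
}

# Squared normalised ellipsoid radius field for a grid, centre and semi-axes.
ellipsoid_r2 <- function(shape, centre, axes) {
  gx <- (seq_len(shape[1]) - centre[1]) / axes[1]
  gy <- (seq_len(shape[2]) - centre[2]) / axes[2]
  gz <- (seq_len(shape[3]) - centre[3]) / axes[3]
  outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
}

# Periodic Gaussian smoothing via FFT; wrap-around edge effects are masked out
# by the caller (texture is only applied inside the brain).
smooth_noise <- function(shape, sd_out, sigma = 1.5) {
  noise <- array(stats::rnorm(prod(shape)), dim = shape)
  ax <- lapply(shape, function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-d^2 / (2 * sigma^2))
  })
  kern <- outer(outer(ax[[1]], ax[[2]], `*`), ax[[3]], `*`)
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) / prod(shape)
  s <- stats::sd(sm)
  if (s > 0) sm <- sm * (sd_out / s)
  sm
}

#' Generate one synthetic head phantom
#'
#' Deterministic given the spec (including its seed): the same spec always
#' yields a bitwise-identical volume. Background voxels are exactly 0, all
#' intensities lie in \[0, 1\], the skull shell and brain interior are
#' disjoint, and every lesion voxel lies inside the brain mask.
#'
#' @param spec a [phantom_spec()].
#' @param id optional identifier attached to the volume.
#' @return A `volume`: list with `intensities` (3D array), `spacing`,
#'   `brain_mask`, `lesion_mask` (logical arrays) and `id`.
#' @export
generate_phantom <- function(spec, id = NULL) {
  validate_phantom_spec(spec)
  shape <- spec$grid_shape
  with_seed(spec$seed, {
    centre <- (shape + 1) / 2
    base_axes <- c(0.8, 1.0, 0.8) * shape / 2
    jitter <- stats::runif(3, 0.85, 1.15)
    outer_axes <- pmin(base_axes * jitter, shape / 2 - 1.5)
    inner_axes <- pmax(outer_axes - 2, 2)  # shell thickness 2 voxels

    r2_out <- ellipsoid_r2(shape, centre, outer_axes)
    r2_in <- ellipsoid_r2(shape, centre, inner_axes)
    skull_mask <- r2_out <= 1 & r2_in > 1
    brain_mask <- r2_in <= 1

    img <- array(0, dim = shape)
    img[skull_mask] <- spec$skull_intensity
    img[brain_mask] <- spec$brain_intensity
    if (spec$texture_noise_sd > 0) {
      tex <- smooth_noise(shape, spec$texture_noise_sd)
      img[brain_mask] <- img[brain_mask] + tex[brain_mask]
    }

    lesion_mask <- array(FALSE, dim = shape)
    lo <- spec$lesion_count_range[1]
    hi <- spec$lesion_count_range[2]
    n_lesions <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (n_lesions > 0L) {
      deep <- which(r2_in <= 0.6)
      for (i in seq_len(n_lesions)) {
        c_idx <- deep[sample.int(length(deep), 1L)]
        c_pos <- arrayInd(c_idx, shape)
        radii <- stats::runif(3, 2, 4)
        blob <- ellipsoid_r2(shape, as.numeric(c_pos), radii) <= 1 & brain_mask
        lesion_mask <- lesion_mask | blob
      }
      img[lesion_mask] <- spec$lesion_intensity
    }

    img[img < 0] <- 0
    img[img > 1] <- 1
    img[!brain_mask & !skull_mask] <- 0
    new_volume(img, spec$spacing, brain_mask = brain_mask,
               lesion_mask = lesion_mask, id = id)
  })
}

#' Generate a cohort of phantoms with derived seeds
#'
#' Per-item seeds are derived deterministically from `base_seed` via
#' [derive_seed()], so the same `(spec, count, base_seed)` always reproduces
#' the same cohort, and items differ from each other.
#'
#' @param spec a [phantom_spec()]; its own `seed` field is replaced per item.
#' @param count number of phantoms (>= 1).
#' @param base_seed integer seed for the cohort.
#' @param id_prefix prefix for volume identifiers.
#' @return A list of `volume` objects.
#' @export
generate_cohort <- function(spec, count, base_seed = spec$seed,
                            id_prefix = "phantom") {
  abort_if(!is_scalar_number(count) || count < 1, "count must be >= 1")
  count <- as.integer(count)
  lapply(seq_len(count), function(i) {
    s <- spec
    s$seed <- derive_seed(base_seed, i)
    generate_phantom(s, id = sprintf("%s_%03d", id_prefix, i))
  })
}

#' Tabulate a cohort as a manifest tibble
#'
#' @param cohort list of `volume` objects.
#' @param paths,mask_paths optional file paths to record (as written by
#'   [write_cohort()]).
#' @return A tibble with columns `id`, `path`, `mask_path`, `n_lesion_voxels`.
#' @export
cohort_manifest <- function(cohort, paths = NA_character_,
                            mask_paths = NA_character_) {
  tibble::tibble(
    id = vapply(cohort, function(v) v$id %||% NA_character_, character(1)),
    path = paths,
    mask_path = mask_paths,
    n_lesion_voxels = vapply(cohort, function(v) {
      if (is.null(v$lesion_mask)) 0L else as.integer(sum(v$lesion_mask))
    }, integer(1))
  )
}
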