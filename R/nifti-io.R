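# NIfTI reading/writing via RNifti. Volumes travel with spacing in the header;
# masks are written as uint8 images alongside.

#' Write a volume (and its masks) as NIfTI
#'
#' @param v a `volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param write_masks also write `<stem>_brainmask` / `<stem>_lesionmask`
#'   images for any masks present.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_volume_nifti <- function(v, path, write_masks = TRUE) {
  img <- RNifti::asNifti(v$intensities)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  out <- c(image = path)
  if (write_masks) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- sub(paste0("^", gsub("([.()\\[\\]])", "\\\\\\1", stem)), "", path)
    for (m in c("brain_mask", "lesion_mask")) {
      if (!is.null(v[[m]])) {
        mpath <- paste0(stem, "_", gsub("_", "", m), ext)
        mimg <- RNifti::asNifti(array(as.integer(v[[m]]), dim = dim(v[[m]])))
        RNifti::pixdim(mimg) <- v$spacing
        RNifti::writeNifti(mimg, mpath)
        out[[m]] <- mpath
      }
    }
  }
  invisible(out)
}

#' Read a volume from NIfTI
#'
#' @param path image path.
#' @param brain_mask_path,lesion_mask_path optional mask image paths.
#' @param id optional identifier.
#' @return A `volume`.
#' @export
read_volume_nifti <- function(path, brain_mask_path = NULL,
                              lesion_mask_path = NULL, id = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  read_mask <- function(p) {
    if (is.null(p)) return(NULL)
    array(as.array(RNifti::readNifti(p)) > 0.5, dim = dim(img))
  }
  new_volume(array(as.numeric(img), dim = dim(img)), spacing,
             brain_mask = read_mask(brain_mask_path),
             lesion_mask = read_mask(lesion_mask_path), id = id)
}

#' Write a cohort to a directory with a CSV manifest
#'
#' @param cohort list of `volume` objects.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return The manifest tibble (also written as `manifest.csv` in `dir`).
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- character(length(cohort))
  mask_paths <- rep(NA_character_, length(cohort))
  for (i in seq_along(cohort)) {
    id <- cohort[[i]]$id %||% sprintf("vol_%03d", i)
    paths[i] <- file.path(dir, paste0(id, ext))
    written <- write_volume_nifti(cohort[[i]], paths[i])
    if ("lesion_mask" %in% names(written)) mask_paths[i] <- written[["lesion_mask"]]
  }
  manifest <- cohort_manifest(cohort, paths = paths, mask_paths = mask_paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
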