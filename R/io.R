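#' Quantify a scan from co-registered NIfTI volumes
#'
#' Reads activity, atlas-label and grey-matter-mask volumes (which must share
#' one voxel grid; no resampling is attempted), computes ROI means inside the
#' mask, optionally applies region-based partial-volume correction, and
#' returns the perfusion-index vector.
#'
#' @param activity_path,labels_path,gm_path Paths to NIfTI volumes.
#' @param atlas An `atlas_spec`.
#' @param psf_fwhm_mm PSF width for partial-volume correction; 0 skips it.
#' @param voxel_size_mm Voxel edge length in mm.
#' @param denominator PI reference, `"rest"` or `"global"`.
#' @param patient,state Scan identifiers.
#' @return A [perfusion_vector()].
#' @export
quantify_nifti <- function(activity_path, labels_path, gm_path, atlas,
                           psf_fwhm_mm = 0, voxel_size_mm = 1,
                           denominator = "rest",
                           patient = NA_character_, state = "interictal") {
  act <- as.array(RNifti::readNifti(activity_path))
  lab <- as.array(RNifti::readNifti(labels_path))
  gm <- as.array(RNifti::readNifti(gm_path))
  tab <- compute_roi_means(act, lab, gm, atlas, patient = patient, state = state)
  if (psf_fwhm_mm > 0) {
    tab <- pvc_region_gtm(tab, lab, gm, psf_fwhm_mm, voxel_size_mm)
  }
  perfusion_index(tab, denominator = denominator)
}

#' Write a phantom to NIfTI files
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory.
#' @param voxel_size_mm Voxel edge length recorded in the headers.
#' @return Invisibly, the three paths written (activity, labels, gm_mask).
#' @export
write_phantom_nifti <- function(phantom, dir, voxel_size_mm = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("activity.nii.gz", "labels.nii.gz", "gm_mask.nii.gz"))
  pix <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(phantom$activity, pixdim = pix), paths[1])
  RNifti::writeNifti(RNifti::asNifti(phantom$labels, pixdim = pix), paths[2])
  RNifti::writeNifti(RNifti::asNifti(phantom$gm_mask, pixdim = pix), paths[3])
  invisible(paths)
}
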