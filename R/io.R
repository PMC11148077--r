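# Thin NIfTI wrappers around RNifti with a diagonal RAS affine.

#' Write a 3-D array as NIfTI
#'
#' @param volume Numeric 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm.
#' @param origin mm coordinate of voxel (1,1,1) (RAS).
#' @return Invisibly, `path`.
#' @export
write_nifti_volume <- function(volume, path, voxel_size = 1, origin = c(0, 0, 0)) {
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- origin
  img <- RNifti::asNifti(volume)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array.
#' @export
read_nifti_volume <- function(path) {
  as.array(RNifti::readNifti(path))
}

#' Read/write the subject feature table
#'
#' TSV with fixed column names (`subject_id`, the 16 IdC metrics, pontine
#' means, `age`, `sex`, `education_years`, `ptau181`, `ab42`,
#' `csf_mri_delay_days`, `apoe4`).
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_subject_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
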