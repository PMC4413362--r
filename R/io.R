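#' Read a 4D BOLD NIfTI file
#'
#' @param path NIfTI-1 file.
#' @param tr Repetition time (s); taken from the header when NULL.
#' @param brain_mask Optional logical 3D mask or mask NIfTI path.
#' @return A [bold_run()] in raw units.
#' @export
read_bold <- function(path, tr = NULL, brain_mask = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) stop("expected a 4D NIfTI in ", path)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  if (is.character(brain_mask)) brain_mask <- read_mask(brain_mask)
  bold_run(unclass(img)[, , , , drop = FALSE], tr = tr,
           affine = unclass(RNifti::xform(img)), brain_mask = brain_mask)
}

#' Read a binary mask NIfTI file
#' @param path NIfTI-1 file.
#' @return Logical 3D array with the image affine in `attr(, "affine")`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  m <- unclass(img) != 0
  if (length(dim(m)) > 3) dim(m) <- dim(m)[1:3]
  attr(m, "affine") <- unclass(RNifti::xform(img))
  m
}

#' Write a 3D map/mask or 4D run as NIfTI
#'
#' @param x 3D or 4D numeric or logical array (NAs written as 0).
#' @param path Output path (.nii or .nii.gz).
#' @param affine 4x4 voxel-to-world affine.
#' @param tr Repetition time (s), stored in the 4th pixdim of 4D images.
#' @return Invisibly, `path`.
#' @export
write_map <- function(x, path, affine, tr = 1) {
  x <- x * 1
  x[is.na(x)] <- 0
  img <- RNifti::asNifti(x)
  # pixdim must carry the voxel size (and TR) before the xform is
  # attached, otherwise the scaling is dropped on write; one value per
  # image dimension
  pd <- c(sqrt(colSums(affine[1:3, 1:3]^2)), tr)[seq_along(dim(x))]
  RNifti::pixdim(img) <- pd
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write a 4x4 affine as a plain-text matrix (FLIRT-style)
#' @param path Text file with 4 rows of 4 numbers.
#' @return 4x4 matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4, 4))) stop("expected a 4x4 matrix in ", path)
  m
}

#' Write a frame-aligned regressor as TSV
#' @param regressor A [co2_regressor()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_regressor <- function(regressor, path) {
  d <- data.frame(
    frame = seq_len(regressor$n_frames),
    time_s = regressor$t_start + (seq_len(regressor$n_frames) - 0.5) *
      regressor$tr,
    co2_mmhg = regressor$values)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
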