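#' 4D BOLD run container
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param tr Repetition time (s).
#' @param affine 4x4 voxel-to-world (mm) transform over 0-based voxel
#'   indices; defaults to a grid-centred scaling by `voxel_mm`.
#' @param brain_mask Logical 3D array; voxels outside are ignored.
#' @param voxel_mm Voxel size (mm), used only when `affine` is missing.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, affine = NULL, brain_mask = NULL,
                     voxel_mm = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 4, tr > 0)
  if (dim(data)[4] < 10) stop("BOLD run needs >= 10 frames")
  if (is.null(affine)) affine <- centered_affine(dim(data)[1:3], voxel_mm)
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(data)[1:3])
  stopifnot(all(dim(brain_mask) == dim(data)[1:3]))
  structure(list(data = data, tr = tr, affine = affine,
                 brain_mask = brain_mask, n_frames = dim(data)[4]),
            class = "bold_run")
}

#' Grid-centred voxel-to-world affine
#'
#' Maps 0-based voxel index i to world coordinate
#' `(i - (n - 1)/2) * voxel_mm`, putting the world origin at the grid
#' centre so the x = 0 plane is the left/right midline of a symmetric grid.
#'
#' @param shape Integer vector of 3 grid dimensions.
#' @param voxel_mm Voxel size (mm), length 3.
#' @return A 4x4 affine matrix.
#' @export
centered_affine <- function(shape, voxel_mm) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(voxel_mm, 3)
  a[1:3, 4] <- -(shape - 1) / 2 * voxel_mm
  a
}

.flat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

#' Convert a raw BOLD run to %BOLD
#'
#' Each in-brain voxel time series is divided by its temporal mean and
#' multiplied by 100, so every in-mask voxel has temporal mean exactly 100
#' and fluctuations are percent signal change. Voxels whose temporal mean
#' is not positive cannot be normalised; they are removed from the brain
#' mask with a warning. Out-of-mask voxels are zeroed.
#'
#' @param data 4D raw-signal array, or a [bold_run()] in raw units.
#' @param brain_mask Logical 3D array (ignored if `data` is a `bold_run`
#'   carrying one). If missing, an Otsu threshold on the temporal-mean
#'   image is used (requires the EBImage package).
#' @param tr,affine Passed to [bold_run()] when `data` is a bare array.
#' @return A [bold_run()] in %BOLD units.
#' @export
to_percent_bold <- function(data, brain_mask = NULL, tr = 2, affine = NULL) {
  if (inherits(data, "bold_run")) {
    run <- data
    if (!is.null(brain_mask)) run$brain_mask <- brain_mask
  } else {
    run <- bold_run(data, tr = tr, affine = affine, brain_mask = brain_mask)
  }
  y <- .flat(run$data)
  mu <- rowMeans(y)
  if (is.null(brain_mask) && !inherits(data, "bold_run"))
    run$brain_mask <- auto_brain_mask(array(mu, dim(run$data)[1:3]))
  mask <- as.vector(run$brain_mask)
  bad <- mask & !(is.finite(mu) & mu > 0)
  if (any(bad)) {
    warning(sum(bad), " in-mask voxel(s) with non-positive temporal mean ",
            "removed from the brain mask")
    mask[bad] <- FALSE
  }
  out <- matrix(0, nrow(y), ncol(y))
  out[mask, ] <- 100 * y[mask, ] / mu[mask]
  dim(out) <- dim(run$data)
  run$data <- out
  run$brain_mask <- array(mask, dim(run$data)[1:3])
  run
}

#' Otsu brain mask from a temporal-mean image
#'
#' Bimodal threshold between air and tissue intensity on the mean image.
#'
#' @param mean_img 3D array of temporal means.
#' @return Logical 3D array.
#' @export
auto_brain_mask <- function(mean_img) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("auto_brain_mask needs the EBImage package; supply brain_mask instead")
  rng <- range(mean_img)
  if (diff(rng) == 0) stop("mean image is constant; cannot threshold")
  scaled <- (mean_img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mean_img > rng[1] + th * diff(rng)
}

#' Remove per-voxel linear drift
#'
#' Fits an intercept-plus-slope line to every in-mask voxel series by
#' ordinary least squares, subtracts it, and restores the voxel temporal
#' mean (100 for %BOLD data). Scanner drift over a breath-hold run is well
#' approximated as linear; removing it upstream keeps the CVR GLM design
#' to an intercept and the CO2 regressor only.
#'
#' @param run A [bold_run()].
#' @return The detrended [bold_run()].
#' @export
detrend_linear <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  n <- run$n_frames
  if (n < 3) stop("need >= 3 frames to detrend")
  y <- .flat(run$data)
  mask <- as.vector(run$brain_mask)
  X <- cbind(1, seq_len(n))
  ym <- t(y[mask, , drop = FALSE])
  res <- stats::lm.fit(X, ym)$residuals
  y[mask, ] <- t(res) + rowMeans(y[mask, , drop = FALSE])
  dim(y) <- dim(run$data)
  run$data <- y
  run
}

#' Global %BOLD signal
#'
#' Per-frame mean over all in-brain voxels.
#'
#' @param run A [bold_run()] in %BOLD units.
#' @return Numeric vector of length `run$n_frames`.
#' @export
global_signal <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  if (!any(run$brain_mask)) stop("empty brain mask")
  colMeans(.flat(run$data)[as.vector(run$brain_mask), , drop = FALSE])
}

#' Frame-wise displacement from rigid-body motion parameters
#'
#' Power-style FWD: the sum of absolute frame-to-frame changes in the three
#' translations plus the three rotations converted to arc length on a
#' sphere of `head_radius` mm. The first frame has FWD 0 by convention and
#' is excluded from the mean.
#'
#' @param mp Matrix or data frame with 6 columns: translations tx, ty, tz
#'   (mm) then rotations rx, ry, rz (radians), one row per frame.
#' @param head_radius Sphere radius (mm) for rotation-to-displacement
#'   conversion.
#' @param n_frames Optional expected frame count; mismatch is an error.
#' @return List with `fwd` (per-frame, mm) and `mean_fwd` (mm, frames
#'   2..N).
#' @export
framewise_displacement <- function(mp, head_radius = 50, n_frames = NULL) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6) stop("motion parameters must have 6 columns")
  if (nrow(mp) < 2) stop("need >= 2 frames of motion parameters")
  if (!is.null(n_frames) && nrow(mp) != n_frames)
    stop("motion parameter rows (", nrow(mp),
         ") do not match frame count (", n_frames, ")")
  d <- abs(diff(mp))
  fwd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
             head_radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fwd = fwd, mean_fwd = mean(fwd[-1]))
}

#' Read 6-column rigid-body motion parameters from a TSV file
#'
#' Columns: tx, ty, tz in mm then rx, ry, rz in radians (headerless or
#' with a header row).
#'
#' @param path File path.
#' @return A numeric matrix with 6 columns.
#' @export
read_motion_params <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "[\t ,]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  as.matrix(utils::read.table(path, header = header))
}
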