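#' Peri-infarct shell by millimetre dilation
#'
#' All voxels whose centre lies within `radius_mm` (Euclidean distance in
#' world millimetres, honouring anisotropic voxels) of any lesion voxel
#' centre, minus the lesion itself. Implemented as binary dilation with
#' the exact set of integer voxel offsets whose world-space length does
#' not exceed the radius.
#'
#' @param lesion Logical 3D lesion mask.
#' @param affine 4x4 voxel-to-world (mm) affine of the grid.
#' @param radius_mm Dilation radius (mm); the 10 mm default defines the
#'   peri-infarct region.
#' @return Logical 3D peri-infarct mask (empty, with a warning, if the
#'   lesion is empty).
#' @export
make_peri_infarct <- function(lesion, affine, radius_mm = 10) {
  lesion <- lesion != 0
  dims <- dim(lesion)
  if (!any(lesion)) {
    warning("empty lesion mask: peri-infarct mask is empty")
    return(array(FALSE, dims))
  }
  M <- affine[1:3, 1:3]
  vox <- sqrt(colSums(M^2))
  K <- ceiling(radius_mm / vox)
  off <- as.matrix(expand.grid(di = -K[1]:K[1], dj = -K[2]:K[2],
                               dk = -K[3]:K[3]))
  keep <- colSums((M %*% t(off))^2) <= radius_mm^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  idx <- which(lesion, arr.ind = TRUE)
  out <- array(FALSE, dims)
  for (r in seq_len(nrow(off))) {
    sh <- idx
    sh[, 1] <- sh[, 1] + off[r, 1]
    sh[, 2] <- sh[, 2] + off[r, 2]
    sh[, 3] <- sh[, 3] + off[r, 3]
    ok <- sh[, 1] >= 1 & sh[, 1] <= dims[1] &
      sh[, 2] >= 1 & sh[, 2] <= dims[2] &
      sh[, 3] >= 1 & sh[, 3] <= dims[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  out & !lesion
}

#' Healthy-tissue mask by set subtraction
#'
#' The hemisphere voxels inside the brain that belong to neither the
#' lesion nor the peri-infarct shell.
#'
#' @param hemi,lesion,peri,brain Logical 3D masks on the same grid.
#' @return Logical 3D mask `hemi & brain & !lesion & !peri`.
#' @export
make_healthy <- function(hemi, lesion, peri, brain) {
  dims <- dim(hemi)
  if (!all(vapply(list(lesion, peri, brain),
                  function(m) identical(dim(m), dims), logical(1))))
    stop("mask grids do not match")
  out <- (hemi != 0) & (brain != 0) & !(lesion != 0) & !(peri != 0)
  if (!any(out))
    warning("healthy mask is empty: hemisphere fully covered by lesion and shell")
  out
}

.vox_to_std <- function(affine, affine_to_std) affine_to_std %*% affine

#' Mirror a mask into the opposite hemisphere
#'
#' The mask is taken to a left/right-symmetric standard space (via the
#' image affine composed with `affine_to_std`), reflected about the
#' midline x = 0 plane, and brought back to the image grid, all with
#' nearest-neighbour sampling so the mask stays binary. Under an identity
#' standard transform on a grid-centred affine this reduces to exact
#' reversal of the x index, and applying it twice is the identity.
#'
#' @param mask Logical 3D mask.
#' @param affine 4x4 voxel-to-world affine of the grid (0-based indices).
#' @param affine_to_std 4x4 world-to-standard-space affine (e.g. a FLIRT
#'   subject-to-MNI matrix); identity by default.
#' @return Logical 3D mask of the homologous region.
#' @export
flip_homologous <- function(mask, affine, affine_to_std = diag(4)) {
  if (abs(det(affine_to_std)) < 1e-12 || abs(det(affine)) < 1e-12)
    stop("affine must be invertible")
  dims <- dim(mask)
  T <- .vox_to_std(affine, affine_to_std)
  FL <- diag(c(-1, 1, 1, 1))
  # output voxel -> standard -> reflect -> back -> source voxel
  B <- solve(T) %*% FL %*% T
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  src <- round(B %*% rbind(t(idx), 1))[1:3, , drop = FALSE]
  ok <- src[1, ] >= 0 & src[1, ] <= dims[1] - 1 &
    src[2, ] >= 0 & src[2, ] <= dims[2] - 1 &
    src[3, ] >= 0 & src[3, ] <= dims[3] - 1
  out <- array(FALSE, dims)
  lin_out <- 1 + idx[ok, 1] + dims[1] * (idx[ok, 2] + dims[2] * idx[ok, 3])
  lin_src <- 1 + src[1, ok] + dims[1] * (src[2, ok] + dims[2] * src[3, ok])
  out[lin_out] <- (mask != 0)[lin_src]
  out
}

#' Split the brain into left and right hemispheres
#'
#' Voxels with standard-space x < 0 are left, x > 0 right; voxels on the
#' midline plane (|x| below tolerance) belong to neither.
#'
#' @param brain Logical 3D brain mask.
#' @param affine 4x4 voxel-to-world affine of the grid.
#' @param affine_to_std 4x4 world-to-standard affine; identity by default.
#' @param tol Midline exclusion half-width (mm).
#' @return List with logical masks `l_hemi` and `r_hemi`.
#' @export
hemisphere_split <- function(brain, affine, affine_to_std = diag(4),
                             tol = 1e-6) {
  dims <- dim(brain)
  T <- .vox_to_std(affine, affine_to_std)
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  x <- drop(T[1, ] %*% rbind(t(idx), 1))
  b <- as.vector(brain != 0)
  list(l_hemi = array(b & x < -tol, dims),
       r_hemi = array(b & x > tol, dims))
}

#' Build the full stroke mask family
#'
#' From a lesion mask and a brain mask, constructs the eight-region family
#' used for regional CVR comparison: left lesion, its peri-infarct shell
#' (millimetre dilation minus the lesion), the remaining left-hemisphere
#' healthy tissue, both hemispheres, and the right-hemisphere homologues of
#' the three left masks obtained by standard-space left/right reflection.
#' The three left regions partition `l_hemi & brain` by construction, and
#' likewise on the right up to reflection rounding.
#'
#' @param lesion Logical 3D lesion mask (expected left-lateralised; a
#'   midline-crossing lesion triggers a warning).
#' @param brain Logical 3D brain mask.
#' @param affine 4x4 voxel-to-world affine.
#' @param affine_to_std 4x4 world-to-standard affine; identity by default.
#' @param radius_mm Peri-infarct dilation radius (mm).
#' @param r_lesion Optional right-hemisphere lesion mask subtracted from
#'   `r_hemi`-derived healthy tissue (for the minority of patients with
#'   small additional right-sided infarcts).
#' @return An object of class `mask_set` with fields `l_lesion`,
#'   `l_peri_infarct`, `l_healthy`, `l_hemi`, `r_hemi`, `r_lesion`,
#'   `r_peri_infarct`, `r_healthy`, plus `affine` and `affine_to_std`.
#' @export
build_mask_set <- function(lesion, brain, affine, affine_to_std = diag(4),
                           radius_mm = 10, r_lesion = NULL) {
  lesion <- lesion != 0; brain <- brain != 0
  hemis <- hemisphere_split(brain, affine, affine_to_std)
  if (any(lesion & hemis$r_hemi))
    warning("lesion crosses the midline into the right hemisphere; ",
            "voxels outside l_hemi are kept in l_lesion but not in the ",
            "left partition")
  peri <- make_peri_infarct(lesion, affine, radius_mm)
  l_lesion <- lesion
  l_peri <- peri & hemis$l_hemi & brain
  l_healthy <- make_healthy(hemis$l_hemi, lesion, peri, brain)
  r_lesion_h <- flip_homologous(l_lesion, affine, affine_to_std)
  r_peri_h <- flip_homologous(l_peri, affine, affine_to_std)
  r_healthy <- flip_homologous(l_healthy, affine, affine_to_std)
  if (!is.null(r_lesion)) {
    r_lesion_h <- r_lesion_h | (r_lesion != 0)
    r_healthy <- r_healthy & !(r_lesion != 0)
    r_peri_h <- r_peri_h & !(r_lesion != 0)
  }
  structure(list(l_lesion = l_lesion, l_peri_infarct = l_peri,
                 l_healthy = l_healthy, l_hemi = hemis$l_hemi,
                 r_hemi = hemis$r_hemi, r_lesion = r_lesion_h,
                 r_peri_infarct = r_peri_h, r_healthy = r_healthy,
                 affine = affine, affine_to_std = affine_to_std,
                 radius_mm = radius_mm),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  for (nm in c("l_lesion", "l_peri_infarct", "l_healthy", "l_hemi",
               "r_lesion", "r_peri_infarct", "r_healthy", "r_hemi"))
    cat(sprintf("  %-15s %6d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}
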