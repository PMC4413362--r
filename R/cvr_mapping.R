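#' Delay search grid specification
#'
#' Exhaustive temporal-shift search grid used to align the CO2 regressor
#' with the BOLD signal: delays from `min_delay` to `max_delay` in `step`
#' increments. The default covers -15 s to +15 s in 0.1 s steps (301
#' candidate delays).
#'
#' @param min_delay,max_delay Search bounds (s).
#' @param step Grid step (s).
#' @return An object of class `delay_search_spec`.
#' @export
delay_search_spec <- function(min_delay = -15, max_delay = 15, step = 0.1) {
  stopifnot(min_delay < max_delay, step > 0)
  structure(list(min_delay = min_delay, max_delay = max_delay, step = step),
            class = "delay_search_spec")
}

.delay_grid <- function(spec) {
  # integer-indexed grid avoids floating-point drift in seq()
  seq(round(spec$min_delay / spec$step),
      round(spec$max_delay / spec$step)) * spec$step
}

#' Single-voxel GLM of BOLD on a regressor
#'
#' Ordinary least squares of `y` on an intercept and `x`. The slope is the
#' response amplitude (e.g. %BOLD per mmHg when `x` is the CO2 regressor);
#' `r2` is the fraction of variance of `y` explained.
#'
#' @param y Response series.
#' @param x Regressor series (numeric, or a [co2_regressor()]).
#' @return List with `beta` (slope), `intercept` and `r2`.
#' @export
fit_glm_single <- function(y, x) {
  if (inherits(x, "co2_regressor")) x <- x$values
  stopifnot(length(y) == length(x), length(y) >= 3)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate regressor: x is constant")
  yc <- y - mean(y)
  b <- sum(xc * yc) / sxx
  syy <- sum(yc^2)
  r2 <- if (syy == 0) 0 else sum(xc * yc)^2 / (sxx * syy)
  list(beta = b, intercept = mean(y) - b * mean(x), r2 = r2)
}

#' Regressor builder closure over a CO2 series
#'
#' Returns a function of one argument `delay` producing the frame-aligned
#' regressor at that delay, for use with [optimize_global_delay()] and
#' [fit_voxopt()]. Shifting happens on the high-resolution series grid
#' (0.1 s by default), not by whole frames.
#'
#' @param series A [co2_series()] (HRF-convolved end-tidal model).
#' @param tr Repetition time (s).
#' @param n_frames Number of retained frames.
#' @param t_start Start time of the first retained frame (s).
#' @return A function `delay -> co2_regressor`.
#' @export
co2_regressor_builder <- function(series, tr, n_frames, t_start = 0) {
  force(series); force(tr); force(n_frames); force(t_start)
  function(delay) resample_to_frames(series, tr, n_frames,
                                     delay = delay, t_start = t_start)
}

#' Optimise the global CO2-to-BOLD delay
#'
#' Physiological transit (lung to brain) and the capnograph sampling line
#' delay the recorded end-tidal trace relative to the BOLD response. The
#' delay is found by exhaustive grid search: the regressor is shifted over
#' the grid and the delay whose GLM explains the most variance in the
#' global BOLD signal is returned. Exact ties are broken toward the
#' smallest absolute delay; a maximum on the grid boundary triggers a
#' warning since the true delay may lie outside the search range.
#'
#' @param regressor_builder A function `delay -> co2_regressor`, e.g. from
#'   [co2_regressor_builder()].
#' @param global_signal Global %BOLD series (see [global_signal()]).
#' @param spec A [delay_search_spec()].
#' @return List with `delay` (s), `r2`, and the full search `grid`/`r2_grid`.
#' @export
optimize_global_delay <- function(regressor_builder, global_signal,
                                  spec = delay_search_spec()) {
  stopifnot(length(global_signal) >= 3)
  delays <- .delay_grid(spec)
  r2 <- vapply(delays, function(d) {
    x <- regressor_builder(d)$values
    if (stats::var(x) == 0) return(NA_real_)
    fit_glm_single(global_signal, x)$r2
  }, numeric(1))
  if (all(is.na(r2))) stop("delay search failed: all fits degenerate")
  m <- max(r2, na.rm = TRUE)
  cand <- which(r2 == m)
  best <- cand[order(abs(delays[cand]), delays[cand])][1]
  if (best == 1L || best == length(delays))
    warning("optimal delay ", delays[best],
            " s lies on the search boundary; consider widening the range")
  list(delay = delays[best], r2 = m, grid = delays, r2_grid = r2)
}

#' Per-voxel CVR estimation result
#'
#' @param method One of "GlobOpt", "VoxOpt", "RHsig".
#' @param beta 3D amplitude map (%BOLD/mmHg for GlobOpt/VoxOpt; percent of
#'   the reference amplitude for RHsig); NA outside the mask.
#' @param r2 3D variance-explained map in \[0, 1\]; NA outside the mask.
#' @param delay 3D absolute delay map in s (VoxOpt) or NULL.
#' @param delay_rel 3D delay map relative to the global optimum (VoxOpt).
#' @param global_delay Scalar globally optimised delay (s); NA for RHsig.
#' @param mask Logical 3D analysis mask.
#' @return An object of class `cvr_result`.
#' @export
cvr_result <- function(method, beta, r2, delay = NULL, delay_rel = NULL,
                       global_delay = NA_real_, mask = NULL) {
  method <- match.arg(method, c("GlobOpt", "VoxOpt", "RHsig"))
  structure(list(method = method, beta = beta, r2 = r2, delay = delay,
                 delay_rel = delay_rel, global_delay = global_delay,
                 mask = mask),
            class = "cvr_result")
}

#' @export
print.cvr_result <- function(x, ...) {
  v <- x$r2[x$mask]
  cat(sprintf("%s CVR result: %d voxels, median R2 %.3f", x$method,
              sum(x$mask), stats::median(v, na.rm = TRUE)))
  if (!is.na(x$global_delay))
    cat(sprintf(", global delay %.1f s", x$global_delay))
  cat("\n")
  invisible(x)
}

# In-mask voxel matrix (frames x voxels) and its column-centred form.
.mask_matrix <- function(run) {
  y <- t(.flat(run$data)[as.vector(run$brain_mask), , drop = FALSE])
  yc <- sweep(y, 2, colMeans(y))
  list(y = y, yc = yc, syy = colSums(yc^2))
}

.fill_map <- function(values, mask) {
  m <- array(NA_real_, dim(mask))
  m[mask] <- values
  m
}

#' Globally delay-optimised CVR fit (GlobOpt)
#'
#' The CO2 regressor, shifted once by the globally optimised delay, is
#' fitted to every in-brain voxel time series with a GLM (intercept +
#' regressor). The slope map is CVR in %BOLD per mmHg end-tidal CO2.
#'
#' @param run A preprocessed (%BOLD, detrended) [bold_run()].
#' @param regressor A [co2_regressor()] at the globally optimised delay.
#' @return A [cvr_result()] with a scalar `global_delay`.
#' @export
fit_globopt <- function(run, regressor) {
  stopifnot(inherits(run, "bold_run"), inherits(regressor, "co2_regressor"))
  if (regressor$n_frames != run$n_frames)
    stop("regressor not aligned to run frames")
  x <- regressor$values
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate regressor: x is constant")
  mm <- .mask_matrix(run)
  sxy <- drop(crossprod(mm$yc, xc))
  beta <- sxy / sxx
  r2 <- ifelse(mm$syy > 0, sxy^2 / (sxx * mm$syy), 0)
  cvr_result("GlobOpt", .fill_map(beta, run$brain_mask),
             .fill_map(r2, run$brain_mask),
             global_delay = regressor$applied_delay, mask = run$brain_mask)
}

#' Voxelwise delay-optimised CVR fit (VoxOpt)
#'
#' Repeats the GLM for every delay on a grid of offsets around the globally
#' optimised delay and, per voxel, keeps the delay that explains the most
#' variance. Because the grid contains offset 0, every voxel's R-squared is
#' at least its GlobOpt value. Exact ties are broken toward the smallest
#' absolute offset. Stroke slows regional haemodynamics, so lesional and
#' peri-infarct voxels typically select positive offsets; the slope at the
#' optimum keeps CVR quantitative (%BOLD/mmHg) even in delayed tissue.
#'
#' @param run A preprocessed [bold_run()].
#' @param regressor_builder A function `delay -> co2_regressor` (see
#'   [co2_regressor_builder()]).
#' @param spec A [delay_search_spec()] of offsets relative to
#'   `global_delay`.
#' @param global_delay Globally optimised delay (s) from
#'   [optimize_global_delay()].
#' @return A [cvr_result()] with absolute (`delay`) and relative
#'   (`delay_rel`) per-voxel delay maps.
#' @export
fit_voxopt <- function(run, regressor_builder, spec = delay_search_spec(),
                       global_delay = 0) {
  stopifnot(inherits(run, "bold_run"))
  offsets <- .delay_grid(spec)
  # columns ordered by |offset| so that max.col(ties = "first") implements
  # the smallest-|delay| tie-break
  ord <- order(abs(offsets), offsets)
  offsets <- offsets[ord]
  n <- run$n_frames
  X <- vapply(offsets,
              function(o) regressor_builder(global_delay + o)$values,
              numeric(n))
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  if (all(sxx == 0)) stop("degenerate regressor: constant at all delays")
  mm <- .mask_matrix(run)
  C <- crossprod(mm$yc, Xc)                       # voxels x delays
  r2 <- C^2 / outer(mm$syy, sxx)
  r2[!is.finite(r2)] <- 0
  best <- max.col(r2, ties.method = "first")
  pick <- cbind(seq_len(nrow(r2)), best)
  beta <- C[pick] / sxx[best]
  cvr_result("VoxOpt",
             .fill_map(beta, run$brain_mask),
             .fill_map(r2[pick], run$brain_mask),
             delay = .fill_map(global_delay + offsets[best], run$brain_mask),
             delay_rel = .fill_map(offsets[best], run$brain_mask),
             global_delay = global_delay, mask = run$brain_mask)
}

#' Reference-hemisphere signal CVR fit (RHsig)
#'
#' When no usable end-tidal trace exists, the mean %BOLD series over a
#' reference region assumed free of vascular pathology (typically the
#' entire contralesional right hemisphere) serves as the breath-hold
#' response model. Each voxel is regressed on this reference series; the
#' slope times 100 expresses the voxel's response as a percentage of the
#' reference amplitude, so a voxel identical to the reference scores
#' exactly 100%. No delay optimisation is performed, and the measure is
#' relative rather than quantitative.
#'
#' @param run A preprocessed [bold_run()].
#' @param reference_mask Logical 3D array; must be non-empty and lie within
#'   the brain mask.
#' @return A [cvr_result()] (`beta` in % of reference amplitude; no delay
#'   maps).
#' @export
fit_rhsig <- function(run, reference_mask) {
  stopifnot(inherits(run, "bold_run"))
  if (!any(reference_mask)) stop("empty reference mask")
  if (any(reference_mask & !run$brain_mask))
    stop("reference mask extends outside the brain mask")
  ref <- colMeans(.flat(run$data)[as.vector(reference_mask), , drop = FALSE])
  xc <- ref - mean(ref)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate regressor: reference series is constant")
  mm <- .mask_matrix(run)
  sxy <- drop(crossprod(mm$yc, xc))
  r2 <- ifelse(mm$syy > 0, sxy^2 / (sxx * mm$syy), 0)
  cvr_result("RHsig", .fill_map(100 * sxy / sxx, run$brain_mask),
             .fill_map(r2, run$brain_mask), mask = run$brain_mask)
}
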