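#' Critical R-squared for a single-regressor GLM
#'
#' The R-squared corresponding to an uncorrected significance level
#' `alpha` for a GLM with one regressor plus intercept over `n_frames`
#' time points: `F / (F + n - 2)` with `F` the upper-`alpha` quantile of
#' the F(1, n - 2) distribution. Voxels below this value are treated as
#' showing no breath-hold response. For the canonical 134-frame run at
#' alpha = 0.05 this is 0.0288.
#'
#' @param n_frames Number of time points (>= 4).
#' @param alpha Significance level.
#' @return The critical R-squared, in (0, 1).
#' @examples
#' round(critical_r2(134), 4)  # 0.0288
#' @export
critical_r2 <- function(n_frames, alpha = 0.05) {
  if (n_frames < 4) stop("n_frames must be >= 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  f <- stats::qf(1 - alpha, 1, n_frames - 2)
  f / (f + n_frames - 2)
}

#' Voxel admission threshold specification
#'
#' @param n_frames Run length (time points).
#' @param alpha Uncorrected significance level.
#' @return An object of class `threshold_spec` with the derived `r2_crit`.
#' @export
threshold_spec <- function(n_frames, alpha = 0.05) {
  structure(list(alpha = alpha, n_frames = as.integer(n_frames),
                 r2_crit = critical_r2(n_frames, alpha)),
            class = "threshold_spec")
}

#' Apply the R-squared threshold within a mask
#'
#' Keeps the mask voxels whose GLM R-squared exceeds the critical value,
#' removing voxels with no detectable breath-hold response (e.g. white
#' matter or atrophic tissue) before regional averaging. The threshold is
#' sign-blind: negative responses with good fits are retained.
#'
#' @param result A [cvr_result()].
#' @param mask Logical 3D mask on the result grid.
#' @param spec A [threshold_spec()] (or anything with an `r2_crit` field).
#' @return Logical 3D passing mask.
#' @export
threshold_by_r2 <- function(result, mask, spec) {
  if (!identical(dim(mask), dim(result$r2)))
    stop("mask grid does not match result grid")
  (mask != 0) & !is.na(result$r2) & result$r2 > spec$r2_crit
}

#' Regional summary of a CVR result
#'
#' Per-mask summary used for group comparison: the percentage of mask
#' voxels passing the R-squared threshold, and the mean R-squared
#' (expressed as % variance explained), mean response amplitude and mean
#' delay over the passing voxels only. The unthresholded mean amplitude is
#' also reported for transparency.
#'
#' @inheritParams threshold_by_r2
#' @param name Label for the mask.
#' @return An object of class `region_summary`: list with `mask_name`,
#'   `n_voxels`, `n_passing`, `pct_passing`, `mean_r2_passing` (percent),
#'   `mean_beta_passing`, `mean_delay_passing` (s; NA when the method has
#'   no delay map), `mean_beta_all`.
#' @export
summarize_mask <- function(result, mask, spec, name = "mask") {
  mask <- mask != 0
  n <- sum(mask)
  if (n == 0) {
    warning("empty mask '", name, "': summary is empty")
    return(structure(list(mask_name = name, n_voxels = 0L, n_passing = 0L,
                          pct_passing = NA_real_, mean_r2_passing = NA_real_,
                          mean_beta_passing = NA_real_,
                          mean_delay_passing = NA_real_,
                          mean_beta_all = NA_real_),
                     class = "region_summary"))
  }
  pass <- threshold_by_r2(result, mask, spec)
  np <- sum(pass)
  md <- if (!is.null(result$delay) && np > 0)
    mean(result$delay[pass]) else NA_real_
  structure(list(
    mask_name = name, n_voxels = n, n_passing = np,
    pct_passing = 100 * np / n,
    mean_r2_passing = if (np > 0) 100 * mean(result$r2[pass]) else NA_real_,
    mean_beta_passing = if (np > 0) mean(result$beta[pass]) else NA_real_,
    mean_delay_passing = md,
    mean_beta_all = mean(result$beta[mask], na.rm = TRUE)),
    class = "region_summary")
}

#' Summarise a CVR result over every region of a mask set
#'
#' @param result A [cvr_result()].
#' @param masks A [build_mask_set()] result, or a named list of masks.
#' @param spec A [threshold_spec()].
#' @return A data frame with one row per region.
#' @export
summarize_mask_set <- function(result, masks, spec) {
  nms <- intersect(c("l_lesion", "l_peri_infarct", "l_healthy", "l_hemi",
                     "r_lesion", "r_peri_infarct", "r_healthy", "r_hemi"),
                   names(masks))
  if (!length(nms)) nms <- names(masks)
  rows <- lapply(nms, function(nm)
    as.data.frame(unclass(summarize_mask(result, masks[[nm]], spec, nm))))
  do.call(rbind, rows)
}

#' Interhemispheric delay difference
#'
#' Mean passing-voxel delay in a left-hemisphere region minus that of its
#' right-hemisphere homologue; 0 means no interhemispheric delay
#' difference. Positive values indicate a slowed response on the left
#' (lesioned) side.
#'
#' @param left,right_homologue [summarize_mask()] results carrying delay
#'   means (i.e. from a VoxOpt result).
#' @return Delay difference in seconds.
#' @export
delay_difference <- function(left, right_homologue) {
  if (is.na(left$mean_delay_passing) || is.na(right_homologue$mean_delay_passing))
    stop("delay difference not applicable: summaries carry no delay ",
         "(only VoxOpt estimates voxelwise delays)")
  left$mean_delay_passing - right_homologue$mean_delay_passing
}

#' Group comparison of per-subject regional values
#'
#' Student paired t-test for matched sessions or conditions, Welch
#' unpaired t-test for independent groups, and a one-sample Student t-test
#' against zero when `y` is absent (used for interhemispheric delay
#' differences). Two-sided p-values; no multiple-comparison correction. A
#' zero-variance contrast is flagged `degenerate` (t is 0 or +/-Inf as the
#' mean dictates) rather than erroring, so constructed phantoms with exact
#' ties are handled.
#'
#' @param x Numeric vector of per-subject values.
#' @param y Optional second vector (group or session).
#' @param paired Use a paired test (requires matched order, equal length).
#' @param mu Null value for the one-sample test.
#' @return List with `t`, `p`, `df`, `mean_x`, `mean_y`, `sd_x`, `sd_y`,
#'   `method` and `degenerate`.
#' @export
compare_groups <- function(x, y = NULL, paired = FALSE, mu = 0) {
  if (length(x) < 2) stop("need >= 2 values per group")
  out <- list(mean_x = mean(x), sd_x = stats::sd(x),
              mean_y = if (is.null(y)) NA_real_ else mean(y),
              sd_y = if (is.null(y)) NA_real_ else stats::sd(y),
              degenerate = FALSE)
  if (is.null(y)) {
    d <- x - mu
    out$method <- "one-sample t"
  } else if (paired) {
    if (length(x) != length(y)) stop("paired test needs equal lengths")
    d <- x - y
    out$method <- "paired t"
  } else {
    if (length(y) < 2) stop("need >= 2 values per group")
    tt <- stats::t.test(x, y, var.equal = FALSE)
    out$t <- unname(tt$statistic); out$p <- tt$p.value
    out$df <- unname(tt$parameter); out$method <- "Welch unpaired t"
    return(out)
  }
  if (stats::sd(d) == 0) {
    out$degenerate <- TRUE
    out$t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    out$p <- if (mean(d) == 0) 1 else 0
    out$df <- length(d) - 1
    return(out)
  }
  tt <- stats::t.test(d, mu = 0)
  out$t <- unname(tt$statistic); out$p <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}
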