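#' Run the full breath-hold CVR analysis chain
#'
#' From a raw capnograph trace and a motion-corrected raw BOLD run:
#' builds the HRF-convolved end-tidal CO2 model, converts the BOLD run to
#' %BOLD and removes linear drift, optimises the global CO2-to-BOLD
#' delay against the global signal, fits the requested estimators, and
#' (when a mask set is supplied) produces thresholded regional summaries.
#'
#' @param bold_raw A [bold_run()] in raw units, or a 4D array.
#' @param trace A [capno_trace()].
#' @param paradigm A [make_paradigm()] describing the task and TR.
#' @param brain_mask Logical 3D mask (required if `bold_raw` carries
#'   none).
#' @param affine Voxel-to-world affine when `bold_raw` is a bare array.
#' @param methods Subset of `c("globopt", "voxopt", "rhsig")`.
#' @param global_search [delay_search_spec()] for the global delay.
#' @param voxel_search [delay_search_spec()] of per-voxel offsets around
#'   the global optimum.
#' @param hrf An [hrf_spec()].
#' @param alpha Significance level for the R-squared admission threshold.
#' @param mask_set Optional [build_mask_set()] for regional summaries.
#' @param reference_mask Reference region for RHsig; defaults to
#'   `mask_set$r_hemi`.
#' @return List with `series`, `prep` (preprocessed run), `global_signal`,
#'   `global_delay`, `global_r2`, `threshold`, `results` (named
#'   [cvr_result()] list) and `summaries` (named list of data frames).
#' @export
run_bh_pipeline <- function(bold_raw, trace, paradigm,
                            brain_mask = NULL, affine = NULL,
                            methods = c("globopt", "voxopt", "rhsig"),
                            global_search = delay_search_spec(),
                            voxel_search = delay_search_spec(),
                            hrf = hrf_spec(), alpha = 0.05,
                            mask_set = NULL, reference_mask = NULL) {
  methods <- match.arg(methods, c("globopt", "voxopt", "rhsig"),
                       several.ok = TRUE)
  n <- paradigm_n_frames(paradigm)
  series <- build_co2_series(trace, paradigm, hrf)
  prep <- to_percent_bold(bold_raw, brain_mask, tr = paradigm$tr,
                          affine = affine)
  if (prep$n_frames != n)
    stop("BOLD run has ", prep$n_frames, " frames but the paradigm ",
         "retains ", n)
  prep <- detrend_linear(prep)
  gs <- global_signal(prep)
  builder <- co2_regressor_builder(series, paradigm$tr, n,
                                   t_start = paradigm$drop_first * paradigm$tr)
  gopt <- optimize_global_delay(builder, gs, global_search)

  if (is.null(reference_mask) && !is.null(mask_set))
    reference_mask <- mask_set$r_hemi & prep$brain_mask
  results <- list()
  if ("globopt" %in% methods)
    results$globopt <- fit_globopt(prep, builder(gopt$delay))
  if ("voxopt" %in% methods)
    results$voxopt <- fit_voxopt(prep, builder, voxel_search, gopt$delay)
  if ("rhsig" %in% methods) {
    if (is.null(reference_mask))
      stop("rhsig needs a reference_mask (or a mask_set with r_hemi)")
    results$rhsig <- fit_rhsig(prep, reference_mask)
  }
  thr <- threshold_spec(n, alpha)
  summaries <- if (!is.null(mask_set))
    lapply(results, summarize_mask_set, masks = mask_set, spec = thr)
  list(series = series, prep = prep, global_signal = gs,
       global_delay = gopt$delay, global_r2 = gopt$r2, threshold = thr,
       results = results, summaries = summaries)
}
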