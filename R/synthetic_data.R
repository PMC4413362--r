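#' Simulate a breath-hold capnograph recording
#'
#' Generates a 200 Hz CO2 trace following the cyclic paradigm: during
#' breathing blocks the trace is a train of expiration bumps whose
#' end-tidal maxima equal `baseline_petco2`; during each end-expiration
#' hold no air flows and the trace is flat near zero; the first breath
#' after a hold is the quick exhalation, peaking at `baseline_petco2 +
#' hold_boost` to carry the CO2 accumulated during apnea. A short
#' breathing tail after the final hold lets its boost be measured.
#' Additive Gaussian sensor noise, clipped at 0 mmHg.
#'
#' @param paradigm A [make_paradigm()].
#' @param baseline_petco2 End-tidal CO2 of normal breathing (mmHg).
#' @param hold_boost End-tidal increase after each hold (mmHg).
#' @param breath_rate Breathing rate (Hz); breaths per block are rounded
#'   to fit the block exactly.
#' @param noise_sd Sensor noise standard deviation (mmHg).
#' @param seed RNG seed; a fixed seed reproduces the trace exactly.
#' @param fs Sampling rate (Hz).
#' @param tail_s Breathing tail after the final hold (s).
#' @return A [capno_trace()].
#' @export
simulate_capnograph <- function(paradigm, baseline_petco2 = 40,
                                hold_boost = 8, breath_rate = 0.25,
                                noise_sd = 0.3, seed = 1, fs = 200,
                                tail_s = 12) {
  stopifnot(inherits(paradigm, "bh_paradigm"), breath_rate > 0)
  breathe_s <- paradigm$natural_s + paradigm$paced_s
  if (round(breathe_s * breath_rate) < 1)
    stop("breath_rate too slow for the breathing block")
  total <- paradigm$total_s + tail_s
  time <- seq(0, total, by = 1 / fs)
  val <- numeric(length(time))

  bump_block <- function(t_rel, L, first_peak, peak) {
    n_b <- max(1L, round(L * breath_rate))
    tb <- L / n_b
    b <- pmin(floor(t_rel / tb), n_b - 1)
    peaks <- c(first_peak, rep(peak, n_b - 1))[b + 1]
    tau <- (t_rel - b * tb) / tb
    peaks * (1 - cos(2 * pi * tau)) / 2
  }

  for (cyc in seq_len(paradigm$n_cycles)) {
    cs <- (cyc - 1) * paradigm$cycle_s
    in_block <- time >= cs & time < cs + breathe_s
    first_peak <- if (cyc == 1) baseline_petco2 else
      baseline_petco2 + hold_boost
    val[in_block] <- bump_block(time[in_block] - cs, breathe_s,
                                first_peak, baseline_petco2)
    # hold: no expired air reaches the cannula
    val[time >= cs + breathe_s & time < cs + paradigm$cycle_s] <- 0
  }
  in_tail <- time >= paradigm$total_s
  val[in_tail] <- bump_block(time[in_tail] - paradigm$total_s, tail_s,
                             baseline_petco2 + hold_boost, baseline_petco2)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    val <- pmax(0, val + stats::rnorm(length(val), 0, noise_sd))
  }
  capno_trace(time, val)
}

#' Ground-truth stroke CVR phantom
#'
#' Builds a symmetric ellipsoidal brain on a grid with a left-lateralised
#' spherical lesion, derives the full mask family through the same
#' millimetre-dilation and reflection operations as the analysis (so the
#' generated labels round-trip exactly), and assigns regional CVR
#' amplitude and haemodynamic delay values. Defaults reflect typical
#' patient-cohort values: healthy tissue 0.29 %BOLD/mmHg, peri-infarct
#' 0.21, lesion 0.19, with the peri-infarct response delayed by +1.2 s and
#' the lesion by +1.8 s relative to the contralesional side. Right-side
#' homologue regions carry the healthy amplitude and no extra delay, so
#' interhemispheric differences have known ground truth.
#'
#' @param shape Grid dimensions; the default 32 x 38 x 32 at
#'   3.5 x 3.5 x 3 mm voxels approximates a whole-brain EPI acquisition.
#' @param voxel_mm Voxel size (mm).
#' @param lesion_centre_mm Lesion centre in world mm (x negative = left);
#'   `NULL` for a lesion-free control phantom.
#' @param lesion_radius_mm Lesion radius (mm).
#' @param cvr_healthy,cvr_peri,cvr_lesion Regional CVR truth
#'   (%BOLD/mmHg).
#' @param cvr_l_healthy Override for left-hemisphere healthy tissue (used
#'   to model diffusely reduced ipsilesional CVR); defaults to
#'   `cvr_healthy`.
#' @param delay_peri,delay_lesion Regional response delays (s) added on
#'   top of the global delay in the left peri-infarct and lesion masks.
#' @param global_delay_s Global CO2-to-BOLD delay (s): lung-to-brain
#'   transit plus the capnograph sampling line.
#' @param cvr_jitter,delay_jitter Within-region Gaussian jitter SDs.
#' @param noise_sd Per-voxel white BOLD noise SD (%BOLD).
#' @param drift_slope Linear scanner drift (%BOLD per frame).
#' @param baseline_petco2,hold_boost Capnograph truth (mmHg).
#' @param seed RNG seed for jitter.
#' @return An object of class `phantom_truth` with fields `cvr_map`,
#'   `delay_map` (absolute CO2-to-BOLD delay, s), `region_labels`,
#'   `masks` (a `mask_set`), `brain`, `affine`, and the scalar parameters.
#' @export
make_stroke_phantom <- function(shape = c(32, 38, 32),
                                voxel_mm = c(3.5, 3.5, 3),
                                lesion_centre_mm = c(-30, 8, 4),
                                lesion_radius_mm = 12,
                                cvr_healthy = 0.29, cvr_peri = 0.21,
                                cvr_lesion = 0.19,
                                cvr_l_healthy = cvr_healthy,
                                delay_peri = 1.2, delay_lesion = 1.8,
                                global_delay_s = 3,
                                cvr_jitter = 0, delay_jitter = 0,
                                noise_sd = 0.8, drift_slope = 0.01,
                                baseline_petco2 = 40, hold_boost = 8,
                                seed = 1) {
  affine <- centered_affine(shape, voxel_mm)
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  w <- t(affine %*% rbind(t(idx), 1))[, 1:3]
  semi <- 0.9 * shape * voxel_mm / 2
  brain <- array(rowSums(sweep(w, 2, semi, "/")^2) <= 1, shape)

  if (is.null(lesion_centre_mm) || lesion_radius_mm <= 0) {
    lesion <- array(FALSE, shape)
  } else {
    d2 <- rowSums(sweep(w, 2, lesion_centre_mm)^2)
    lesion <- array(d2 <= lesion_radius_mm^2, shape) & brain
    if (!any(lesion)) stop("lesion sphere contains no brain voxels")
  }
  masks <- if (any(lesion))
    build_mask_set(lesion, brain, affine) else {
      hs <- hemisphere_split(brain, affine)
      structure(list(l_lesion = lesion, l_peri_infarct = array(FALSE, shape),
                     l_healthy = hs$l_hemi, l_hemi = hs$l_hemi,
                     r_hemi = hs$r_hemi, r_lesion = array(FALSE, shape),
                     r_peri_infarct = array(FALSE, shape),
                     r_healthy = hs$r_hemi, affine = affine,
                     affine_to_std = diag(4), radius_mm = 10),
                class = "mask_set")
    }

  cvr <- array(NA_real_, shape)
  cvr[brain] <- cvr_healthy
  cvr[masks$l_healthy] <- cvr_l_healthy
  cvr[masks$l_peri_infarct] <- cvr_peri
  cvr[masks$l_lesion] <- cvr_lesion
  delay <- array(NA_real_, shape)
  delay[brain] <- global_delay_s
  delay[masks$l_peri_infarct] <- global_delay_s + delay_peri
  delay[masks$l_lesion] <- global_delay_s + delay_lesion
  if (cvr_jitter > 0 || delay_jitter > 0) {
    set.seed(seed)
    nb <- sum(brain)
    if (cvr_jitter > 0)
      cvr[brain] <- cvr[brain] + stats::rnorm(nb, 0, cvr_jitter)
    if (delay_jitter > 0)
      delay[brain] <- delay[brain] + stats::rnorm(nb, 0, delay_jitter)
  }
  structure(list(
    cvr_map = cvr, delay_map = delay,
    region_labels = list(healthy = masks$l_healthy | masks$r_healthy,
                         peri_infarct = masks$l_peri_infarct,
                         lesion = masks$l_lesion,
                         left = masks$l_hemi, right = masks$r_hemi),
    masks = masks, brain = brain, affine = affine, shape = shape,
    voxel_mm = voxel_mm, noise_sd = noise_sd, drift_slope = drift_slope,
    baseline_petco2 = baseline_petco2, hold_boost = hold_boost,
    global_delay_s = global_delay_s, seed = seed),
    class = "phantom_truth")
}

#' Simulate a 4D BOLD run from phantom truth
#'
#' Forward model per voxel v with baseline signal B_v:
#' `y_v(t) = B_v * (1 + (cvr_v * dx(t - delay_v) + drift * t_c + g(t) +
#' e_v(t)) / 100)`, where `dx` is the HRF-convolved end-tidal CO2 model
#' centred on its run mean, `t_c` the mean-centred frame index, `g` a
#' noise process shared by all brain voxels (scanner/physiological
#' fluctuations that survive spatial averaging) and `e_v` white voxel
#' noise. The multiplicative-on-baseline form means %BOLD conversion and
#' detrending invert the model exactly, so noiseless recovery is an
#' identity up to the 0.1 s delay grid. Per-voxel delays are applied on
#' the high-resolution series grid.
#'
#' @param truth A [make_stroke_phantom()] result.
#' @param series The HRF-convolved CO2 model as a [co2_series()] (e.g.
#'   from [build_co2_series()] on the simulated trace).
#' @param paradigm The [make_paradigm()] used for frame timing.
#' @param noise_sd Per-voxel white noise SD (%BOLD); defaults to the
#'   truth's value.
#' @param global_noise_sd Shared noise SD (%BOLD); overridden when
#'   `target_global_r2` is given.
#' @param target_global_r2 If set, the shared noise SD is derived
#'   analytically so the expected variance explained in the global signal
#'   by the CO2 regressor equals this value
#'   (`sd = sd(signal) * sqrt(1/r2 - 1)`).
#' @param drift_slope Linear drift (%BOLD/frame).
#' @param baseline Mean raw signal level (arbitrary scanner units); a mild
#'   through-slice gradient is applied so %BOLD conversion is non-trivial.
#' @param seed RNG seed; fixed seed gives a bit-identical run.
#' @return A [bold_run()] in raw units with the phantom's brain mask and
#'   affine; the realised noise parameters are stored in `$sim`.
#' @export
simulate_bold <- function(truth, series, paradigm,
                          noise_sd = truth$noise_sd,
                          global_noise_sd = 0, target_global_r2 = NULL,
                          drift_slope = truth$drift_slope,
                          baseline = 500, seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(series, "co2_series"))
  n <- paradigm_n_frames(paradigm)
  t_start <- paradigm$drop_first * paradigm$tr
  if (max(co2_series_times(series)) < t_start + (n - 0.5) * paradigm$tr - 15)
    stop("CO2 series does not cover the run")
  brain <- as.vector(truth$brain)
  nb <- sum(brain)
  cvr <- truth$cvr_map[truth$brain]
  dly <- truth$delay_map[truth$brain]

  x0 <- resample_to_frames(series, paradigm$tr, n,
                           delay = truth$global_delay_s,
                           t_start = t_start)$values
  m0 <- mean(x0)
  ud <- sort(unique(dly))
  dx <- vapply(ud, function(d)
    resample_to_frames(series, paradigm$tr, n, delay = d,
                       t_start = t_start)$values - m0, numeric(n))
  cls <- match(dly, ud)

  tc <- seq_len(n) - (n + 1) / 2
  if (!is.null(target_global_r2)) {
    stopifnot(target_global_r2 > 0, target_global_r2 < 1)
    # regional mix of delayed responses that the global signal will carry
    sig <- drop(dx %*% vapply(seq_along(ud),
                              function(k) sum(cvr[cls == k]), numeric(1))) / nb
    sig <- sig - stats::fitted(stats::lm(sig ~ tc))   # detrended, as analysed
    global_noise_sd <- stats::sd(sig) * sqrt(1 / target_global_r2 - 1)
  }

  if (!is.null(seed)) set.seed(seed)
  g <- if (global_noise_sd > 0) stats::rnorm(n, 0, global_noise_sd) else
    numeric(n)
  pct <- dx[, cls, drop = FALSE]                      # frames x voxels
  pct <- sweep(pct, 2, cvr, "*")
  pct <- pct + drift_slope * tc + g
  if (noise_sd > 0)
    pct <- pct + matrix(stats::rnorm(n * nb, 0, noise_sd), n, nb)

  kz <- (slice.index(truth$brain, 3) - 1)[truth$brain]
  B <- baseline * (1 + 0.1 * (kz / max(1, truth$shape[3] - 1) - 0.5))
  raw <- matrix(0, length(brain), n)
  raw[brain, ] <- B * t(1 + pct / 100)
  dim(raw) <- c(truth$shape, n)
  run <- bold_run(raw, tr = paradigm$tr, affine = truth$affine,
                  brain_mask = truth$brain)
  run$sim <- list(noise_sd = noise_sd, global_noise_sd = global_noise_sd,
                  drift_slope = drift_slope, seed = seed,
                  global_delay_s = truth$global_delay_s)
  run
}

#' Simulate a full phantom session (capnograph + BOLD)
#'
#' Draws one capnograph recording and one BOLD run from a phantom truth.
#' The BOLD forward model uses the CO2 series derived from the simulated
#' trace through the package's own regressor chain, so with zero noise the
#' analysis inverts the simulation exactly.
#'
#' @param truth A [make_stroke_phantom()].
#' @param paradigm A [make_paradigm()].
#' @param seed Session seed (trace and BOLD noise derive from it).
#' @param capno_noise_sd Capnograph sensor noise (mmHg).
#' @param ... Passed to [simulate_bold()] (e.g. `noise_sd`,
#'   `target_global_r2`).
#' @return List with `trace`, `series` (HRF-convolved CO2 model), and
#'   `bold` (raw-unit [bold_run()]).
#' @export
phantom_session <- function(truth, paradigm = make_paradigm(), seed = 1,
                            capno_noise_sd = 0.3, ...) {
  trace <- simulate_capnograph(paradigm, truth$baseline_petco2,
                               truth$hold_boost, noise_sd = capno_noise_sd,
                               seed = seed)
  series <- build_co2_series(trace, paradigm)
  # offset keeps the BOLD noise stream disjoint from neighbouring session
  # seeds (the trace and the run must not share randomness)
  bold <- simulate_bold(truth, series, paradigm, seed = seed + 500000L, ...)
  list(trace = trace, series = series, bold = bold)
}
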