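---
title: "Breath-hold CVR mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold CVR mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science inside `bhcvr`: the signal model each
stage assumes, the tunable parameters and why their defaults are what they
are, what the synthetic phantom does and does not emulate, and the
numerical decisions that were genuinely open.

## The measurement

A cyclic breath-hold task — 14 s natural breathing, 16 s visually paced
breathing, then a 15 s end-expiration hold, repeated six times over 270 s
— raises arterial CO2 a few mmHg per cycle. CO2 is a potent vasodilator,
so each hold produces a global BOLD response of a few tenths of a percent
per mmHg. Cerebrovascular reactivity (CVR) is the slope of that
relationship. Because task compliance varies (especially in patients),
the stimulus is not assumed but measured: a nasal-cannula capnograph
records the CO2 partial pressure throughout, and the per-breath end-tidal
values quantify the arterial CO2 surrogate each subject actually
achieved. End-expiration holds are used because they start from a
reproducible lung volume and avoid the biphasic response of
end-inspiration holds; the quick exhalation demanded immediately after
each hold is what makes the accumulated CO2 measurable.

## End-tidal regressor construction

`detect_end_tidal()` implements the peak detection. The trace is smoothed
with a 0.25 s moving average (long enough to suppress cardiogenic
oscillations at 200 Hz, far shorter than a breath), local maxima are kept
if their topographic prominence exceeds 1 mmHg (sensor noise is a few
tenths of a mmHg; true expiration plateaus rise tens of mmHg above the
inspiratory trough), and maxima closer than 1.5 s are merged, keeping the
higher — no plausible breathing rate exceeds 40 breaths/min during this
task. The end-tidal *amplitude* is then read from the raw trace within
±0.25 s of the detected peak, so smoothing affects only localisation,
never the measured pressure. All three parameters are exposed.

`interpolate_breath_hold()` joins successive end-tidal values by straight
lines; across each hold window the line runs from the final pre-hold
breath to the post-hold quick exhalation, and any spurious maxima inside a
hold (no expiration occurs there) are discarded first. Linear
interpolation between non-hold breaths was an open choice (nearest-breath
steps were the alternative); linear was chosen because end-tidal CO2
drifts smoothly on the 4 s breath scale and a step function would inject
spurious high-frequency power into the regressor.

`convolve_hrf()` applies the canonical double-gamma haemodynamic response
function (peak at 6 s, undershoot at 16 s, dispersions 1 s,
peak:undershoot ratio 6, 32 s support, 0.1 s resolution). The discrete
kernel is normalised to unit area, which is what makes the convolution
*scale invariant*: a sustained end-tidal step of A mmHg converges to an
output of A mmHg, so the fitted slope remains a quantitative %BOLD/mmHg
measure rather than an arbitrary-units one. The input is padded at its
start with its first value, so a trace already at steady state produces no
onset transient.

## BOLD preprocessing

The pipeline consumes a motion-corrected 4D run and does three things, in
the order %BOLD conversion → linear detrend → global signal:

- `to_percent_bold()` divides each in-brain voxel by its temporal mean and
  multiplies by 100, so every voxel has mean exactly 100 and fluctuations
  are percent signal change. Voxels with non-positive means cannot be
  normalised and are dropped from the mask with a warning.
- `detrend_linear()` removes a per-voxel least-squares line and restores
  the mean. Scanner drift over a 4.5 min run is well approximated as
  linear; removing it here keeps the CVR GLM design to an intercept plus
  the CO2 regressor only.
- `global_signal()` is the per-frame mean over the brain mask.

Whether the global signal should be computed before or after detrending
is not determined by the method; computing it after means the delay
search below is not distracted by drift, and the GLM residual structure
matches the voxelwise fits. **No spatial smoothing is applied anywhere**
— smoothing would leak CVR estimates between lesioned and healthy tissue,
which is precisely the contrast of interest; a test asserts that a
spatial delta pattern survives preprocessing untouched.

Head motion is summarised by the Power-style frame-wise displacement
(sum of absolute frame-to-frame translation changes plus rotation changes
converted to arc length on a 50 mm sphere), the standard single-number
motion report for these runs.

## The three estimators

The recorded CO2 trace lags the BOLD response it drives: alveolar
diffusion, lung-to-brain transit, and metres of capnograph sampling line
together contribute several seconds with either sign relative to the
scanner clock. All delay handling happens on the 0.1 s series grid —
shifting the high-resolution CO2 model and resampling at frame midpoints —
never by whole-frame shifts, because the TR (2 s) is coarse relative to
the 1–2 s pathological delays of interest.

- **GlobOpt**: exhaustive search of τ over [−15, +15] s in 0.1 s steps,
  maximising the variance the shifted regressor explains in the global
  signal; then one GLM per voxel at that τ. Exact ties break toward the
  smallest |τ| (the least-surprising physiology), and a boundary optimum
  triggers a warning since the true delay may lie outside the window.
- **VoxOpt**: the same grid of offsets re-centred on the global optimum,
  searched per voxel; the per-voxel best delay, its offset, and the slope
  and R² at that delay are stored. Since offset 0 is on the grid, VoxOpt
  R² ≥ GlobOpt R² at every voxel, a dominance property the tests assert.
  Absolute voxel delays may therefore reach the global optimum ±15 s;
  both bounds are configurable if a ±15 s absolute clamp is preferred.
- **RHsig**: each voxel regressed on the mean %BOLD series of the entire
  contralesional right hemisphere, slope × 100. It needs no capnograph,
  but it is a *relative* measure (the reference scores 100% by
  construction), performs no delay optimisation, and is biased toward the
  hemisphere that supplies its regressor.

Negative slopes are retained everywhere: CVR can genuinely invert in
pathology (vascular steal), and the admission threshold below is on R²
only, sign-blind.

## Mask algebra

From a manually delineated lesion mask: the **peri-infarct** shell is all
voxels whose centre lies within 10 mm — Euclidean distance in world
millimetres, honouring anisotropic voxels — of a lesion voxel, minus the
lesion. The 10 mm dilation is computed with the exact set of integer
voxel offsets whose world-space length is ≤ 10 mm, so the result equals a
brute-force distance scan (a test checks this). Millimetres rather than
voxel counts were chosen because the acquisition grid (3.5 × 3.5 × 3 mm)
is anisotropic. **Healthy** tissue is the remaining hemisphere-and-brain
voxels. **Homologues** are obtained by taking each left mask to a
left/right-symmetric standard space, reflecting about the x = 0 midline,
and returning — nearest-neighbour in both directions so masks stay
binary. Voxels exactly on the midline belong to neither hemisphere.
Registration itself (e.g. FLIRT with cost-function masking) is external;
the package consumes a 4×4 affine. Patients with small additional
right-sided lesions are handled by subtracting a supplied right-lesion
mask from the right-hemisphere regions.

## Regional statistics

A voxel enters a regional average only if its GLM explains more variance
than `critical_r2(N, alpha)` = F/(F + N − 2), with F the upper-alpha
quantile of F(1, N − 2). For the canonical 134-frame run at alpha = 0.05
this is 0.0288. The threshold is recomputed from the actual run length
rather than hard-coded, and deliberately uncorrected for multiple
comparisons: it is an admission filter against unresponsive tissue (deep
white matter, post-stroke atrophy), not an inference. Sub-threshold
voxels are excluded from delay averages too, for consistency; the
unthresholded mean amplitude is reported alongside for transparency.

Group machinery: paired Student t-tests for matched sessions or methods,
Welch unpaired for independent groups (unequal variances are likely when
comparing patients with controls), one-sample Student against 0 for
interhemispheric delay differences. Zero-variance contrasts (exact ties
on constructed data) are flagged degenerate rather than erroring.

## The synthetic phantom

`make_stroke_phantom()` builds a symmetric ellipsoidal brain on a
32 × 38 × 32 grid of 3.5 × 3.5 × 3 mm voxels (a whole-brain EPI
acquisition at desk scale; ~15,000 brain voxels), with a 12 mm-radius
spherical lesion centred 30 mm left of the midline. The mask family is
derived through the package's own dilation and reflection operations, so
generated labels round-trip exactly. Regional truth defaults are
patient-cohort-typical values: CVR 0.29 %BOLD/mmHg in healthy tissue,
0.21 in the peri-infarct shell, 0.19 in the lesion; response delays of
+1.2 s (peri-infarct) and +1.8 s (lesion) on top of a 3 s global
CO2-to-BOLD delay; right-side homologues carry healthy values so
interhemispheric contrasts have known ground truth.

`simulate_capnograph()` emits a 200 Hz trace of expiration bumps whose
maxima equal the 40 mmHg baseline, flat near zero during holds, with the
first post-hold breath peaking at baseline + 8 mmHg. The boost magnitude
is a generator choice (exposed as `hold_boost`): typical end-tidal
increases from 15 s holds are several mmHg. Sensor noise is white
Gaussian (0.3 mmHg default), clipped at zero.

`simulate_bold()` is multiplicative on baseline:
`y_v(t) = B_v (1 + [cvr_v·Δx(t − delay_v) + drift·t_c + g(t) + ε_v(t)]/100)`,
with Δx the HRF-convolved end-tidal model centred on its run mean, drift
0.01 %BOLD/frame, ε white voxel noise (0.8 %BOLD default, typical 3 T EPI
thermal noise), and g a noise process *shared by all brain voxels*. The
multiplicative form means %BOLD conversion and detrending invert the
model exactly, making noiseless recovery an identity test up to the 0.1 s
delay grid. The shared component exists because per-voxel white noise
averages away over ~10⁴ voxels and so cannot degrade the *global-signal*
fit the way real physiology does; its standard deviation is derived
analytically from a requested global-signal R²
(`sd(signal)·sqrt(1/R² − 1)`), with 0.38 — a realistic patient-level
value — used throughout the tests.

What the phantom does **not** emulate: head motion, cardiac and
respiratory quasi-periodic noise, HRF shape variation across tissue,
partial-volume effects, irregular lesion geometry, or registration error
(the standard transform is the identity). Passing tests therefore
demonstrate that the estimators invert their own forward model at
realistic noise levels and geometry — necessary, not sufficient, evidence
about real data.

## Numerical choices and problem sizes

- Working resolution 0.1 s everywhere (kernel, interpolation grid, delay
  grids); boundary handling on shifts is constant padding, avoiding run-
  edge transients.
- Delay-grid ties break toward the smallest absolute delay; the
  voxelwise implementation orders grid columns by |offset| and takes the
  first maximum, making the tie-break deterministic and vectorised.
- The GLM detrends the data upstream but not the regressor; the
  regressor's own linear-trend share (≈0.4% of its variance for the
  default paradigm) therefore produces a sub-percent downward amplitude
  bias, visible in the noiseless recovery numbers (0.2888 recovered vs
  0.29 injected) and well inside the 1% recovery tolerance.
- Nearest-neighbour reflection rounds voxel centres; under the identity
  standard transform on the phantom's grid-centred affine it is an exact
  x-index reversal and an involution (tested).
- Tests run the full 32 × 38 × 32 × 134 phantom for acceptance-level
  checks and a 16 × 18 × 16 phantom for unit-level ones; a full ±15 s
  voxel search over the large phantom completes in seconds because all
  delays are fitted as one centred-and-normalised matrix product per run.

## Limitations

End-tidal O2 is not modelled (breath-hold hypoxia is mild and its CBF
effect negligible at these durations); dual-echo acquisitions must be
reduced to a single series upstream; motion correction, distortion
correction and registration are consumed, not performed; and RHsig
values are not comparable across subjects in the way mmHg-scaled CVR is —
it is the fallback for sessions without a usable capnograph trace, not a
replacement.
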