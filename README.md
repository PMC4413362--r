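# bhcvr — breath-hold cerebrovascular reactivity mapping for stroke fMRI

BOLD fMRI is routinely used to track recovery of brain function after
stroke, but the BOLD signal is a vascular readout: if stroke alters
cerebrovascular reactivity (CVR) — the ability of vessels to dilate in
response to a vasoactive stimulus — then longitudinal changes in
task-related BOLD signal can be misread as changes in neural activity.
`bhcvr` implements a quantitative breath-hold CVR mapping pipeline for
exactly this situation: a cyclic breath-hold task raises arterial CO2, the
end-tidal CO2 trace recorded at the nose quantifies the stimulus each
subject actually delivered, and a voxelwise GLM converts the BOLD response
into CVR in %BOLD per mmHg, with explicit handling of the slowed
haemodynamics of lesioned and peri-infarct tissue.

The package is aimed at imaging researchers running longitudinal stroke
fMRI studies who need to decide whether a regional BOLD change is
vascular or neural in origin.

## What it computes

**End-tidal CO2 regressor.** From a raw capnograph trace (~200 Hz, mmHg):
per-breath end-tidal values by prominence-based peak detection; linear
interpolation across each breath-hold from the last pre-hold breath to the
post-hold quick exhalation; convolution with a unit-area ("scale
invariant") double-gamma haemodynamic response function, so the regressor
keeps the mmHg scale of the stimulus.

**Three delay-aware CVR estimators.** With the %BOLD-converted, linearly
detrended run `y_v(t)` and the CO2 model `x(t)`:

- **GlobOpt** — the delay `τ*` maximising the variance explained in the
  global (whole-brain mean) signal is found by exhaustive search over
  τ ∈ [−15, +15] s in 0.1 s steps; then per voxel
  `y_v(t) = β_v · x(t − τ*) + intercept`. `β_v` is CVR in %BOLD/mmHg.
- **VoxOpt** — the same search repeated per voxel around `τ*`; the delay
  explaining the most variance in that voxel is kept, along with `β_v` at
  that delay. Recovers quantitative CVR in tissue with slowed responses.
- **RHsig** — when no usable CO2 trace exists, the mean %BOLD series of
  the contralesional right hemisphere serves as the response model;
  `β_v × 100` expresses each voxel as a percentage of the reference
  amplitude (the reference itself scores 100%).

**Mask algebra.** From a lesion mask: the 10 mm peri-infarct shell
(Euclidean dilation in world millimetres minus the lesion), remaining
left-hemisphere healthy tissue, hemisphere splits about the standard-space
midline, and right-hemisphere homologues by reflection in a symmetric
standard space.

**Regional statistics.** Voxels enter regional averages only if their GLM
explains more variance than the critical R² = F⁻¹(1−α; 1, N−2) /
(F⁻¹ + N − 2) — 0.0288 for the canonical 134-frame run at α = 0.05 —
then per-mask percentages passing, mean R², mean CVR, mean delay,
interhemispheric delay differences, and paired/Welch/one-sample t-tests
for group and longitudinal comparisons.

**Synthetic stroke phantom.** A fully parameterised generator
(capnograph + 4D BOLD) with known regional CVR, delays, drift and noise,
used as the package's acceptance surface: the pipeline must recover what
the phantom injected.

## Worked example

Simulate a stroke phantom session and run the full pipeline:

```r
library(bhcvr)

paradigm <- make_paradigm()    # 6 x (14 s natural + 16 s paced + 15 s hold)
truth    <- make_stroke_phantom()
session  <- phantom_session(truth, paradigm, seed = 7,
                            target_global_r2 = 0.38)

fit <- run_bh_pipeline(session$bold, session$trace, paradigm,
                       mask_set = truth$masks)

sprintf("Global CO2-to-BOLD delay: %.1f s (R2 = %.2f)",
        fit$global_delay, fit$global_r2)
#> "Global CO2-to-BOLD delay: 2.4 s (R2 = 0.35)"

v <- fit$summaries$voxopt
v[, c("mask_name", "n_voxels", "pct_passing",
      "mean_beta_passing", "mean_delay_passing")]
#>        mask_name n_voxels pct_passing mean_beta_passing mean_delay_passing
#> 1       l_lesion      200         100             0.173               3.51
#> 2 l_peri_infarct      878         100             0.193               3.13
#> 3      l_healthy     6354         100             0.280               2.33
#> 4         l_hemi     7432         100             0.267               2.46
#> 5       r_lesion      200         100             0.280               2.27
#> 6 r_peri_infarct      878         100             0.280               2.32
#> 7      r_healthy     6354         100             0.280               2.34
#> 8         r_hemi     7432         100             0.280               2.33
```

Reading the table: every voxel passes the R² > 0.0288 admission threshold
(`pct_passing`); the recovered CVR (`mean_beta_passing`, %BOLD/mmHg) drops
from healthy tissue (0.28, injected 0.29) to the peri-infarct shell (0.19,
injected 0.21) to the lesion (0.17, injected 0.19) on the left, while the
right-hemisphere homologues stay at healthy levels; and the VoxOpt delay
map (`mean_delay_passing`, s) shows the peri-infarct response lagging its
right homologue by ≈0.8–1.2 s under this noise draw (the injected
difference is +1.2 s).

The same analyses are available from a shell via the thin CLI:

```sh
inst/cli/cvr-bh simulate --out-dir phantom/ --seed 7 --noise-sd 0.8
inst/cli/cvr-bh fit --bold phantom/bold.nii.gz --mask phantom/brain.nii.gz \
    --trace phantom/trace.tsv --lesion phantom/lesion.nii.gz --out-prefix phantom/s1_
```

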