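# synodce

Quantitative dynamic contrast-enhanced MRI (DCE-MRI) analysis of synovitis,
for imaging scientists validating perfusion biomarkers of the knee joint.
The package implements the full analysis chain used to quantify synovial
inflammation in osteoarthritis — and a digital-phantom cohort generator so
the whole chain can be exercised with known ground truth, without any
patient data.

## What it computes

**Pharmacokinetics.** Voxelwise fitting of the extended Tofts model

```
Ct(t) = vp·Cp(t) + Ktrans ∫₀ᵗ Cp(τ)·exp(−(Ktrans/ve)(t−τ)) dτ
```

yielding K^trans (min⁻¹), v_e, v_p and the model-free IAUC₆₀ (mM·s, the
initial area under the concentration curve for 60 s after tissue arrival).
The plasma input Cp is a population-averaged arterial input function
(two Gaussians + decaying sigmoid, Parker population constants as
configurable defaults), divided by (1 − haematocrit). Concentration comes
from inverting the spoiled gradient-echo (SPGR) signal equation against
native T1 maps fitted from variable flip angle images, with relaxivity
r1 = 3.5 L·mmol⁻¹·s⁻¹. The convolution uses the exact piecewise-linear
recursion, so noiseless forward/inverse roundtrips are exact.

**Segmentation.** Semiautomatic delineation of enhancing pannus: the
pre/post-contrast pair is subtracted with a shuffle transform (per voxel,
the minimum absolute difference over a 3×3 in-plane neighbourhood —
tolerant of one-voxel residual misregistration), thresholded by Otsu's
method sampled within the synovial ROI, and intersected with the ROI to
form the volume of enhancing pannus (VEP, mL). Median biomarkers are
extracted per synovial region and whole joint, for both the semiautomatic
(VEP) and manual (full-ROI) arms.

**Validation statistics.** One-way random-effects variance components and
ICC = σ_b²/(σ_b²+σ_w²) with F-pivot confidence intervals; within-subject
SD or CV with data-driven scale selection (Kendall correlation of
variability with magnitude); the smallest detectable difference
SDD = √2×1.96 ≈ 2.77 × wSD (or wCV); RMSCV and Lin's concordance
correlation for observer reproducibility; pooled-SD standardised mean
differences for group discrimination; and counts of subjects whose
longitudinal change exceeds the SDD (responsiveness).

**Synthetic cohorts.** `generate_phantom()` / `generate_subject_images()` /
`generate_cohort()` simulate a two-group longitudinal cohort (default 14 OA
+ 6 healthy volunteers; baseline, 1-month and 6-month visits) with
specified between/within-subject variance structure, SPGR signal
generation, Gaussian or Rician noise, and per-voxel ground truth stored
for every generated image.

## A worked example

```r
library(synodce)

acq <- acquisition_spec(grid_shape = c(32, 32, 8), noise_sd = 0.5)
ph  <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 8)), seed = 2)
st  <- generate_subject_images(ph, acq, haematocrit = 0.42, seed = 3)
an  <- analyze_study(st)
subset(an$biomarkers, region == "whole_joint",
       select = c(biomarker, method, value, n_voxels))
#>    biomarker   method       value n_voxels
#> 8     ktrans semiauto 0.039869229      368
#> 16        ve semiauto 0.300428990      368
#> 24        vp semiauto 0.017873598      368
#> 32    iauc60 semiauto 8.169822615      368
#> 40    ktrans   manual 0.022356155      736
#> 48        ve   manual 0.292685910      736
#> 56        vp   manual 0.005382486      736
#> 64    iauc60   manual 5.151224535      733
#> 72    vep_ml semiauto 9.200000000      368
```

The phantom's enhancing synovium was generated at a whole-joint median
K^trans of 0.040 min⁻¹; the semiautomatic arm reads 0.0399 min⁻¹ from 368
VEP voxels (the 368 truly enhancing voxels, 9.2 mL at 2.5×2.5×4 mm
voxels), while the manual arm dilutes the median with non-enhancing
synovium and reads 0.0224 min⁻¹ — the behaviour that motivates the
semiautomatic segmentation.

A single-voxel fit is a classed model object with the usual methods:

```r
t  <- dynamic_time_grid(acq)
cp <- aif_plasma(t, aif_parameters(bolus_arrival_offset = 5/6), hct = 0.42)
fit <- fit_extended_tofts(extended_tofts_forward(0.039, 0.3, 0.02, cp, t),
                          cp, t)
fit
#> Extended Tofts fit (35 time points, 6 starts)
#> ktrans     ve     vp
#>  0.039  0.300  0.020
#> RSS: 9.167e-32   IAUC60: 8.326 mM.s   arrival: 1 min
coef(fit); predict(fit); plot(fit)
```

`run_pipeline()` orchestrates simulate → T1 map → concentration → fit →
segment → extract → statistics for a whole cohort from a YAML or list
configuration (see `inst/scripts/synodce-pipeline.R` for a command-line
wrapper), writing biomarker, repeatability, group-comparison and
responsiveness CSVs plus a checksummed run manifest.

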