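---
title: "Quantitative DCE-MRI of synovitis: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DCE-MRI of synovitis: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synodce)
```

# The problem

Synovitis — inflammation of the synovial membrane — is common in knee
osteoarthritis and is a plausible treatment target. Dynamic
contrast-enhanced MRI (DCE-MRI) characterises the uptake and washout of a
gadolinium contrast agent in the synovium and yields quantitative
biomarkers of its microvasculature: the volume transfer constant
$K^{trans}$ (min$^{-1}$), the extravascular extracellular volume fraction
$v_e$, the plasma volume fraction $v_p$, and the model-free initial area
under the concentration curve over the first 60 s after tissue arrival
(IAUC$_{60}$, mM·s). For such biomarkers to be usable in experimental
medicine studies they need technical validation: test-retest repeatability,
discrimination between patients and healthy knees, and sensitivity to
change. `synodce` implements the full analysis chain and the validation
statistics, together with a digital-phantom cohort generator so that every
stage can be exercised, end to end, with known ground truth.

# Signal model and relaxometry

All simulated acquisitions and all signal inversions use the spoiled
gradient-echo (SPGR) steady-state equation

$$S = M_0 \sin\alpha\,\frac{1 - E_1}{1 - E_1 \cos\alpha},
  \qquad E_1 = e^{-TR/T_1}.$$

Native $T_1$ is estimated from variable flip angle (VFA) images by the
linearised fit of $S/\sin\alpha$ against $S/\tan\alpha$, whose slope is
$E_1$. The linearised fit is exact on noiseless data and is the package
default; voxels with degenerate regressions (all-zero signal, slope outside
$(0,1)$) are flagged rather than propagated. No $B_1$ correction is applied
— transmit-field inhomogeneity is outside the scope of the phantom study
design, and at 3 T with a knee coil it mainly rescales $T_1$ smoothly.

Dynamic signal is converted to concentration by inverting the SPGR equation
at each time point. $M_0$ is eliminated using the mean pre-bolus baseline
signal together with the native $T_1$ (the number of baseline frames is a
configuration value, default 5), and the fast-water-exchange linear model
$C(t) = (R_1(t) - 1/T_{10})/r_1$ is applied with relaxivity
$r_1 = 3.5\ \mathrm{L\,mmol^{-1}\,s^{-1}}$ (gadoterate at 3 T). Signals
that imply $E_1$ outside $(0,1)$ — possible under noise near the SPGR
ceiling — are flagged invalid at that time point, never silently clipped.
Within the relaxometry code time is in seconds; minutes appear only at the
pharmacokinetic boundary, where the units of $K^{trans}$ live.

# Input function

The plasma input is a population-averaged arterial input function: two
Gaussians plus an exponentially decaying sigmoid, with the widely used
population constants of Parker et al. (2006) as defaults
(`aif_parameters()`). The constants are configuration values, not
hard-coded literals, so a different population curve of the same form can
be supplied. Whole-blood concentration is converted to plasma concentration
with each subject's haematocrit, $C_p = C_b/(1-\mathrm{Hct})$; when no
haematocrit is available 0.42 is used as a population mean. The curve is
zero before the bolus-arrival offset; because it is discontinuous there, a
guard of $10^{-9}$ min keeps grid times that coincide exactly with the
offset on the pre-arrival side regardless of floating-point representation.

The input function is evaluated on the acquisition time grid by default.
Optional temporal supersampling (frame-wise averaging of a finer grid,
`aif_plasma(supersample = )`) is available because the first-pass peak is
narrow relative to a 10 s frame interval; it is off by default so that
simulation and fitting share one discretisation, which makes noiseless
parameter recovery exact and keeps the phantom's ground truth meaningful at
machine precision.

# Pharmacokinetic model

Tissue concentration follows the extended Tofts model

$$C_t(t) = v_p C_p(t) +
  K^{trans}\!\int_0^t C_p(\tau)\, e^{-k_{ep}(t-\tau)}\,d\tau,
  \qquad k_{ep} = K^{trans}/v_e .$$

The convolution is evaluated by the exact recursion for piecewise-linear
$C_p$: each inter-frame segment is integrated in closed form and the
accumulated integral is decayed between frames. Naive quadrature at 10 s
sampling produces discretisation error that visibly biases $K^{trans}$;
the recursion is exact for any piecewise-linear input, which also makes the
constant-input closed form
$C_t = v_p c_0 + v_e c_0 (1 - e^{-K^{trans} t/v_e})$ an independent check
of the implementation. Small $k_{ep}\Delta t$ uses series expansions to
avoid cancellation.

Voxelwise fitting is bounded Levenberg-Marquardt least squares
(`minpack.lm`), restarted from a small grid of initial values
($K^{trans} \in \{0.01, 0.1, 1\}$ min$^{-1}$, $v_e \in \{0.1, 0.5\}$,
$v_p = 0.01$) because the residual surface is multimodal at low SNR; the
lowest-RSS solution is kept. Bounds are $K^{trans} \in [0, 10]$ min$^{-1}$,
$v_e \in (10^{-6}, 10]$, $v_p \in [0, 1]$. $v_e$ is deliberately *not*
capped at 1: supraphysiological estimates occur in poorly conditioned
voxels in practice, and hiding them behind a hard bound would silently bias
medians. Instead each voxel carries a plausibility flag
($v_e \le 1$, $v_p \le 0.5$, $K^{trans} \le 5$ min$^{-1}$). For whole-volume
fitting of high-SNR data, `fit_tofts_volume(init_grid = "auto")` uses a
single data-driven start per voxel, which is an order of magnitude faster
and converges to the same solutions on clean data (the multi-start grid
remains the default for single-voxel fits).

Tissue bolus arrival is detected by a sustained-exceedance rule — the first
time point above the baseline mean plus three baseline standard deviations
that stays above for two consecutive frames — with the first post-baseline
frame as fallback. The rule is deliberately simple and conservative; any
reasonable detector works at the SNRs where IAUC$_{60}$ is meaningful.
IAUC$_{60}$ is a trapezoidal integral over the 60 s following arrival with
linear interpolation at both window endpoints, computed per voxel from the
voxel's own arrival by default (a per-region median arrival can be supplied
instead by passing a common `arrival` to `compute_iauc60()`).

# Segmentation of enhancing pannus

The semiautomatic segmentation subtracts the pre-contrast from the
post-contrast image with a *shuffle transform*: for each voxel of the
post-contrast image, the subtrahend is the pre-contrast value within a
local neighbourhood that minimises the absolute difference, and the signed
minimising difference is kept. Residual misregistration of up to one voxel
therefore vanishes instead of producing rim artefact, and the output
magnitude can never exceed plain subtraction. Ties are broken by smallest
spatial offset, then lexicographic offset order, so results are exactly
reproducible; the neighbourhood is clipped at volume edges.

Two neighbourhood readings of "the adjacent 3 × 3 voxels" are possible; the
package defaults to in-plane 3×3 (9 candidates) because slice thickness
(2–4 mm) far exceeds in-plane voxel size, making through-plane shuffling
anatomically dubious, and offers 3×3×3 by flag.

The signed difference volume is thresholded by Otsu's method — the 256-bin
histogram threshold maximising between-class variance — with the histogram
sampled *within the synovial ROI union only*. Sampling the whole image
would let empty background dominate the histogram, especially on phantoms
with large air regions; restricting to the ROI makes the lower class the
non-enhancing synovium, which is the contrast that matters. A corollary
worth knowing: if essentially *all* ROI voxels enhance, Otsu will split the
enhancing class itself. The volume of enhancing pannus (VEP) is the
intersection of the thresholded mask with the ROI, reported per region and
whole joint in mL (voxel count × voxel volume).

Median biomarker values are extracted per synovial region and for the whole
joint (all regions combined) over the VEP mask (semiautomatic arm) or the
full ROI (manual arm). A region with no contributing voxels yields a
missing value, never zero. Manual segmentation itself is out of scope: the
ROI label map is an input, supplied by the phantom generator or read from a
NIfTI label file.

# Repeatability, discrimination, responsiveness

Test-retest repeatability uses the one-way random-effects decomposition of
paired visits: $\sigma_w^2 = MS_{within}$,
$\sigma_b^2 = \max(0, (MS_{between} - MS_{within})/2)$, with
$ICC = \sigma_b^2/(\sigma_b^2 + \sigma_w^2)$ and the F-pivot confidence
interval (lower bound truncated at 0). The one-way form is the one
consistent with reporting only two variance components; the truncation at
zero mirrors how a negative between-subject estimate is reported as 0.

The within-subject variability is reported on an absolute scale (wSD
$= \sqrt{\sigma_w^2}$) or a relative scale (wCV by the RMS pair method,
$100\sqrt{\mathrm{mean}[(d_i^2/2)/m_i^2]}$), selected by testing Kendall's
$\tau$ between subject means and absolute visit differences at two-sided
$\alpha = 0.05$: significant magnitude-variability correlation selects the
relative scale. The smallest detectable difference is
$\sqrt{2} \times 1.96 \approx 2.77$ times the wSD or wCV — the smallest
change interpretable as genuine with 95% confidence. Observer
reproducibility uses the root-mean-square CV of measurement pairs and Lin's
concordance correlation coefficient with population moments. Group
discrimination is the standardised mean difference (pooled-SD Cohen's d),
and responsiveness is the strict count of subjects whose change exceeds the
SDD (changes expressed as percent of baseline on the relative scale).

# What the phantom generator emulates — and what it does not

`generate_phantom()` builds a knee-*like* digital phantom: seven synovial
regions (suprapatellar, Hoffa's fat pad, medial/lateral perimeniscal,
intercondylar notch, posterior medial/lateral femoral condyles) as
disjoint ellipsoids on a ring around a central bone compartment with a
small fluid pocket. The geometry is deliberately schematic — it carries the
regions' distinct tissue parameters ($K^{trans}$, $v_e$, $v_p$, native
$T_1$, $M_0$), it does not model anatomy. A configurable fraction of
synovial voxels (default 0.5) enhances; the rest have zero transfer and
plasma fraction, emulating non-enhancing synovial tissue within a rough
manual mask.

`generate_subject_images()` forward-simulates the three acquisitions of a
3 T knee DCE protocol (VFA stack at 2/6/14°, TR 4 ms; 35-phase dynamic
series at flip angle 14°; pre/post subtraction pair taken from the dynamic
frames bracketing enhancement). The dynamic frame interval is not part of
the emulated protocol's public description, so it is a configuration value,
default 10 s per phase (≈5.8 min acquisition — typical for 3D SPGR knee
DCE and long enough for washout), with the bolus arriving after 5 baseline
frames. Noise is Gaussian by default (simpler fitting behaviour) with a
Rician option, since magnitude MRI noise is Rician; at zero signal the
Rician magnitude floor is $\sigma\sqrt{\pi/2}$, which the generator
reproduces.

`generate_cohort()` draws a two-group longitudinal cohort (defaults: 14 OA,
6 healthy volunteers; visits at baseline, 1 month and 6 months) with the
test-retest structure the statistics assume: per-subject true whole-joint
$K^{trans}$ levels are group mean + N(0, $\sigma_b$), each visit adds
N(0, $\sigma_w$), and optional true 6-month changes can be assigned per OA
subject. Default variance components are $\sigma_b^2 = 2.1\times10^{-4}$
and $\sigma_w^2 = 2.4\times10^{-5}$ min$^{-2}$, an OA group mean of
0.039 min$^{-1}$ and an HV mean 0.01 min$^{-1}$ lower — whole-joint values
representative of mild-moderate knee OA versus healthy knees. Haematocrits
are N(0.42, 0.02) truncated to (0.2, 0.65). Each subject-visit's enhancing
$K^{trans}$ field is scaled multiplicatively so that the true whole-joint
median equals the drawn level exactly; drawn levels are floored at
$10^{-4}$ min$^{-1}$ to keep them physical.

What the phantom does *not* emulate: realistic anatomy, motion (the shuffle
transform's motion robustness is tested by explicit translations instead),
$B_1$/$B_0$ inhomogeneity, k-space sampling and parallel-imaging
artefacts, partial volume at tissue interfaces, and biological change
beyond the additive level shifts described above. Passing tests therefore
demonstrate that the *analysis* is correct and self-consistent under the
stated signal model — not that it is robust to everything patient data can
contain.

# Numerical choices

* Convolution: exact piecewise-linear recursion with `expm1`-based terms
  and series fallback below $k_{ep}\Delta t = 10^{-4}$.
* VFA fit: linearised regression; voxels flagged, not guessed, when the
  slope leaves $(0,1)$.
* Concentration inversion: invalid $E_1$ flagged per time point; baseline
  reference is the mean of the pre-bolus frames.
* Otsu: 256 bins spanning the sample range; the returned threshold is the
  bin edge; ties resolve to the lowest edge; classification is strictly
  greater-than.
* Shuffle ties: smallest offset, then lexicographic; boundary
  neighbourhoods clipped.
* Seeds: every stochastic operation takes an explicit integer seed;
  identical spec + seed reproduces bit-identical phantoms, images and
  metadata. Per-study seeds are derived from the cohort seed modulo
  $2^{31}-1$.
* Variance components: negative between-subject estimates truncated to 0;
  ICC confidence bounds clamped to $[0, 1]$.

# Problem sizes used in the shipped checks

The package's own verification uses desk-scale problem sizes chosen to make
every check sharp but cheap: voxel-level roundtrips on 35-frame series;
batch parameter recovery over 500 voxels spanning
$K^{trans} \in [0.005, 0.2]$ min$^{-1}$; Monte-Carlo statistics at
$n = 1000$ subjects (variance components), $10^4$ per group (SMD) and 200
replicates (scale-selection size); and a full end-to-end cohort of 12 OA +
6 HV subjects, three visits, on a 32×32×8 grid at high SNR, in which 5 OA
subjects are assigned true 6-month changes of twice the nominal SDD and the
pipeline's responsiveness count is required to equal exactly 5. The
end-to-end construction sets the within-subject truth SD to zero and counts
against the nominal SDD ($2.77\sqrt{\sigma_w^2}$ of the repeatability
specification) — the only construction under which an exact count is a
deterministic claim rather than a coin flip.

# Known limitations

* The ROI-restricted Otsu sample assumes a mixed enhancing/non-enhancing
  ROI; a fully enhancing ROI will be split by its own heterogeneity.
* IAUC$_{60}$ requires the series to extend 60 s beyond arrival; late
  arrivals near the end of a short series are an error, not an
  extrapolation.
* The one-way ICC intentionally attributes all non-subject variance to
  "within"; visit-order effects are not modelled.
* The fast single-start (`init_grid = "auto"`) volume fitting is tuned for
  high-SNR phantom data; for noisy clinical-like data use the multi-start
  grid.
* `ve` estimates at very low $K^{trans}$ are weakly identified; the
  plausibility flag, not a bound, is the guard.

# A worked example

```{r, eval = FALSE}
library(synodce)

acq <- acquisition_spec(grid_shape = c(32, 32, 8), noise_sd = 0.5)
ph  <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 8)), seed = 2)
st  <- generate_subject_images(ph, acq, haematocrit = 0.42, seed = 3)
an  <- analyze_study(st)
an$biomarkers[an$biomarkers$region == "whole_joint", ]

# full cohort with statistics
res <- run_pipeline(list(
  cohort = list(n_oa = 6, n_hv = 3),
  acquisition = list(grid_shape = c(32, 32, 8), noise_sd = 0.5)),
  seed = 1)
res$stats$repeatability
```
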