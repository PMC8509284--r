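---
title: "Quantitative renal MRI of kidney-graft rejection: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative renal MRI of kidney-graft rejection: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renomap)
```

## The analysis problem

Chronic rejection of a transplanted kidney develops inflammation, edema and
interstitial fibrosis. Quantitative MRI probes these changes non-invasively
through three voxel-wise tissue parameters: the longitudinal relaxation time
T1 (sensitive to free water content, edema and fibrosis), the transverse
relaxation time T2 (sensitive to acute edema), and the apparent diffusion
coefficient ADC (restricted water diffusion under increased cellularity or
collagen deposition). Three derived readouts matter:

1. **Compartmental means** in the cortex, the outer stripe (OSOM) and the
   inner stripe (ISOM) of the outer medulla. On ADC maps the two stripes
   cannot be separated anatomically, so their union (OM) is used there.
2. **The cortico-medullary difference** (CMD), per subject the ISOM mean
   minus the cortex mean. The healthy kidney has a strong positive T1 CMD
   because medullary tubules carry more free water; diffuse disease raises
   cortical values preferentially and erodes the CMD.
3. **Whole-kidney ADC histogram heterogeneity.** Rejection is spatially
   patchy — regions of raised and lowered diffusivity sit side by side — so
   dispersion metrics of the whole-kidney ADC distribution (SD, IQR,
   entropy) separate rejecting from non-rejecting grafts even when group
   means do not.

`renomap` implements this pipeline and validates it on a digital phantom,
because imaging data of this kind are rarely deposited. Everything below is
the package's own account of the models it implements and the choices it
makes.

## The digital kidney phantom

### Geometry

The phantom is a single 2-D coronal slice (the data model carries a slice
axis of length 1, so 3-D data are not precluded): three concentric
elliptical bands on a default 128×128 grid with a 35 mm field of view
(0.27 mm in-plane voxels), long axis along x. The cortex is the outermost
band (normalized elliptical radius 0.75–1), the OSOM the middle band
(0.55–0.75) and the ISOM the core (≤0.55). Concentric ellipses rather than
a realistic kidney silhouette are a deliberate simplification: compartment
means, the CMD and all histogram metrics depend only on the voxel
populations per compartment, not on the organ outline, so ROI logic is
exercised identically while the geometry stays parametric and testable.
Band radii and semi-axes are configurable; degenerate bands (zero width)
are rejected.

### Tissue parameter sets

`tissue_parameters()` bundles per-compartment T1/T2/ADC generation values
for five study arms — healthy controls, isogenic grafts (ischemic injury
without rejection) and allogenic grafts (chronic rejection), the grafts at
3 and 6 weeks after transplantation. Controls, for example, carry cortex /
OSOM / ISOM T1 of 1304 / 1283 / 1808 ms, T2 of 44 / 42 / 54 ms and ADC of
1.61 / 1.72 / 1.72 ×10⁻³ mm²/s; allogenic grafts at week 3 carry strongly
raised T1 (1965 / 2134 / 2282 ms). ADC uses one outer-medullary value for
both stripes, mirroring the fact that the stripes are only reported jointly
on ADC maps. Control and isogenic phantoms are piecewise constant — every
tissue voxel carries its compartment value exactly.

### The allograft heterogeneity model

Allogenic ADC fields are a balanced two-class patchy mixture: a white
Gaussian random field is smoothed with a Gaussian kernel (correlation length
`patch_scale_vox`, default 6 voxels ≈ 1.6 mm — a plausible lesion scale for
a ~1 cm mouse kidney; no quantitative spatial statistics are available to
pin it down, so it is exposed in the configuration) and thresholded at zero,
giving two patch classes with equal expected weights. Class means are the
compartment base value ± `adc_delta`, with within-class Gaussian variation
`within_patch_sd`, clipped below at 0.1×10⁻³ mm²/s.

For this mixture the population SD has the closed form
`sqrt(adc_delta² + within_patch_sd²)`, and the IQR follows from numerically
inverting the mixture CDF (`mixture_iqr()`). That second relation matters:
once the SD is fixed, the split between class separation and within-class
spread is the one remaining shape degree of freedom, and the IQR/SD ratio
pins it down — a pure Gaussian has IQR = 1.349·SD, a hard two-point mixture
IQR = 2·SD. The bundled allograft week-3 settings are therefore calibrated
**jointly** to the target SD 0.33 and IQR 0.45 (×10⁻³ mm²/s), giving
`adc_delta ≈ 0.148` and `within_patch_sd ≈ 0.295` — a *mild* bimodality
whose mixture kurtosis (~2.8) is also consistent with the slightly
platykurtic allograft histograms this models. Calibrating instead with a
small within-class SD (say 0.10) would force `adc_delta ≈ 0.31` and a
strongly bimodal field whose IQR is ≈ 2·delta ≈ 0.63 — the right SD but a
far too wide IQR, so that parameterization is not used as a default. The
week-6 targets (SD 0.32, IQR 0.43) have an IQR/SD ratio *below* the
Gaussian 1.349, which no two-class mixture can reach; the calibration then
degenerates to `adc_delta = 0` and pure Gaussian texture of SD 0.32, its
closest family member. The single-constraint closed-form calibrator
(`calibrate_heterogeneity()`, `delta = sqrt(sd² − sigma²)`) remains
available for experiments that fix the within-class spread.

Heterogeneity is modelled on ADC only by default; T2 heterogeneity in
rejecting grafts shows up in the data model only as the wider CMD spread
that the noise already produces, since no spatial model is available for it.
Patch class weights are fixed at 0.5/0.5 in expectation; finite patch counts
make realized weights fluctuate per subject, which is a realistic source of
between-subject variability.

### What the phantom does and does not emulate

All subjects in a cohort share the same generation values: the phantom
emulates measurement noise and (for allografts) spatial heterogeneity, not
biological between-subject variation. Recovered group SEMs are therefore
smaller than real ones, and significance patterns in the simulated study are
*sanity* checks of the statistical layer, not power estimates. Likewise,
non-rejecting kidneys are piecewise constant, so their whole-kidney ADC
dispersion is set entirely by compartment contrast plus measurement noise
(SD ≈ 0.10×10⁻³ mm²/s at the default SNR); real non-rejecting grafts carry
mild biological texture on top, and their reported dispersion (~0.13) is
correspondingly higher than the phantom can produce. Passing tests show the
pipeline recovers what the generator put in — they do not certify
performance on real data with motion, partial volume or segmentation error.

## Signal synthesis

The three acquisitions follow their closed-form magnitude models:

* Inversion recovery with a non-selective pulse and a full-relaxation TR
  term: `S(TI) = |M0 (1 − (1 + η) e^(−TI/T1) + e^(−TR/T1))|`, inversion
  efficiency η = 1 by default (ideal pulse; configurable). The default axis
  is the 13-point TI schedule 30–8000 ms with TR 18000 ms.
* Mono-exponential spin echo, `S = M0 e^(−TE/T2)`, with 7 echoes. Only the
  range 11–77 ms is fixed by the protocol; the echoes are taken as the
  arithmetic progression with spacing 11 ms (configurable).
* Mono-exponential diffusion decay, `S = S0 e^(−b·ADC)`, with 7 b-values
  spanning 0–800 s/mm². The intermediate spacing is not prescribed; the
  default grid is {0, 100, 200, 300, 400, 600, 800}. Noiseless round-trip
  fitting is exact for any grid, so this choice does not move recovery
  results.

Noise is Rician — each voxel becomes `sqrt((s + n₁)² + n₂²)` with
independent Gaussian channels of SD `s0_scale/snr` — because all fitted data
are magnitude images. The default SNR of 40 (defined at the equilibrium
signal) keeps recovered group means within fractions of a percent of truth
at the study group sizes while leaving visible per-voxel noise; at this SNR
the Gaussian approximation to the Rician is excellent wherever the signal is
well above the floor, which the late-echo T2 and high-b ADC samples are not
quite — see the bias notes below.

## Voxel-wise fitting

**T1 (magnitude inversion recovery).** The model `|a − b·e^(−TI/T1)|` is
linear in (a, b) once T1 is fixed, so each voxel is fitted by variable
projection: an exhaustive sweep over candidate polarity restorations (sign
flips of the measurements before each candidate null position, at most one
per TI), each scored over a coarse log-spaced T1 grid (40 points,
100–10000 ms) with the closed-form linear solve, followed by golden-section
refinement of T1 for the winning candidate. This is deterministic, needs no
starting values, and cannot diverge — the failure modes are handled by
masking instead (all-zero voxels are never fitted; implausible or poorly
fitting voxels are masked). The reported T1 is the exponential rate constant
itself: with a single-shot readout there is no Look-Locker correction.

**T2 and ADC.** The primary estimator is weighted log-linear least squares
(weights = squared signal, the first-order variance weighting for
log-transformed magnitude data); non-positive samples are excluded, and
voxels with fewer than 3 usable echoes (T2) or 2 b-values (ADC) are masked.
A nonlinear refinement on the linear scale (amplitude profiled out,
golden-section on the rate) is available behind `fit_options(refine =
"nls")`; on noiseless data the two coincide to numerical precision, so
recovery results are insensitive to the choice.

**Masks, bounds and quality.** Every map carries a per-voxel R² (computed on
the linear scale against the measured magnitudes) and a validity mask:
fitted, finite, inside the plausibility bounds (T1 200–5000 ms, T2
5–500 ms, ADC 0.05–4.0 ×10⁻³ mm²/s) and R² ≥ 0.9. The bounds and the R²
floor are pragmatic defaults, exposed in `fit_options()`; values at the
upper T2 bound are clipped there and masked. Background voxels are excluded
up front by a signal threshold (default: 20% of the robust image maximum).

**Known biases, documented rather than corrected.** Magnitude noise has a
positive floor, so late T2 echoes and high-b DWI samples are biased upward.
At SNR 40 this raises fitted T2 by ~0.7 ms at T2 ≈ 44 ms (≈1.7%) and biases
ADC slightly low (≈0.7%); T1 at 1800 ms is biased high by ≈0.5%. These are
properties of fitting magnitude data with noise-free models; the package
documents them (and its tests budget for them) instead of applying a
noise-floor correction.

## Region statistics and CMD

`region_means()` averages the valid fitted voxels per region (cortex, OSOM,
ISOM, OM, whole kidney); an empty region yields an explicit `NA`, never 0.
The CMD is computed **per subject** as ISOM mean − cortex mean and only then
averaged across a group, matching how mean ± SEM CMD values are reported.
Because the bundled control generation values are integers (T2 44/54 ms),
the control T2 CMD implied by construction is exactly 10 ms, and the
pipeline recovers ≈10 ms; reported group CMDs from per-subject values can
round to 10.5–11 ms, which is worth keeping in mind when comparing.
`subsample_roi()` optionally restricts fitting and averaging to compact
per-compartment sub-ROIs (random center, nearest in-region voxels),
emulating manual ROI placement variability; whole-compartment means are the
default.

## Histogram metrics

The whole-kidney ADC sample (valid fitted voxels inside the kidney) is
summarized by six descriptors. Mean, SD (n−1), skewness and kurtosis are raw
sample moments — kurtosis in the Pearson convention (normal = 3, *not*
excess), because reported values near 3 for near-unimodal data identify that
convention. The IQR is the 75th−25th percentile of the raw values with
linear interpolation. The entropy is computed from the kernel density
estimate: Gaussian kernel, Silverman's rule-of-thumb bandwidth, evaluated on
a fixed 128-point grid over 0–3.5 ×10⁻³ mm²/s, with
`entropy = −Σ pᵢ log pᵢ / log(128)` after normalizing the grid densities to
sum to one — a declared convention giving values in [0, 1]. Entropy values
depend on the grid and bandwidth convention and are **not** comparable
across implementations; only orderings and within-convention contrasts are
meaningful, which is how the package's tests treat them. A `relative_grid`
flag rescales the grid with the data, making the entropy exactly
scale-invariant when that is preferred. KDE on fewer than 50 values is
refused (unstable), and a constant sample gets a bandwidth floored at half
the grid spacing so its density stays a spike.

## Group statistics

`compare_groups()` reproduces the standard reporting layer: Shapiro–Wilk
normality per group (reported, never blocking — the pipeline's simulated
metrics are near-normal by construction), one-way ANOVA with Tukey HSD
pairwise post hoc tests for three or more groups, an equal-variance unpaired
t-test for two groups (the common default of point-and-click statistics
packages; a Welch flag is provided), and a paired t-test for matched
longitudinal designs. Pairwise Tukey p-values are always reported alongside
the omnibus F rather than gated on it, flagged with the usual
`*/**/***` thresholds at 0.05/0.01/0.001. `summary_table()` formats
mean ± SEM with contrast flags against a reference group.

## Orchestration, determinism and problem sizes

`run_study()` executes phantom → synthesis → three fits → region statistics
→ ADC histogram per subject, then the group comparisons, and optionally
writes CSV results, a JSON manifest (package version, master seed, config
hash) and NIfTI intermediates. Per-subject seeds derive from the master seed
by a stable scheme keyed on the cohort identity (not its position in the
configuration), so adding a cohort never perturbs existing subjects, and
every run is bit-reproducible given (config, seed). All file formats are
NIfTI with JSON sidecars (BIDS-flavoured field names) and CSV.

Problem sizes used in validation were chosen to keep everything desk-scale:
full-size recovery experiments use 128×128 phantoms (≈6100 tissue voxels)
with 22 control and 5 allograft subjects; the replicated significance
checks use 64×64 phantoms with compact 120-voxel sub-ROIs per compartment
for the relaxometry fits and 200 independent replicates. Effect sizes at
the bundled generation values are large enough that these reduced sizes
leave the significance patterns unambiguous.

## Known limitations

* No between-subject biological variability in the generator; SEMs and
  significance levels in simulated studies are optimistic (see above).
* Non-rejecting phantoms cannot reproduce the full whole-kidney ADC
  dispersion of real non-rejecting grafts (no within-compartment texture by
  design).
* The Rician noise-floor biases in T2 and ADC are documented, not corrected.
* No motion, EPI distortion, fat signal, stimulated echoes, B1/inversion-
  efficiency mapping, multi-compartment diffusion (IVIM/DTI) or 3-D
  anatomy; registration and segmentation of real images are out of scope.
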