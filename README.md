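# renomap

Quantitative renal MRI simulation, parameter mapping and histogram analysis
for rodent kidney-transplant imaging studies.

Chronic rejection of a kidney graft builds up inflammation, edema and
interstitial fibrosis that conventional imaging sees only qualitatively.
Quantitative MRI turns the same acquisitions into voxel-wise tissue
parameters — the longitudinal and transverse relaxation times T1 and T2 and
the apparent diffusion coefficient (ADC) — that can be compared across
animals and timepoints. Three readouts carry the signal of rejection:

* **Compartmental means.** Regions of interest in the renal cortex, the outer
  stripe (OSOM) and inner stripe (ISOM) of the outer medulla; for ADC the two
  stripes are not separable, so the whole outer medulla (OM) is used.
* **The cortico-medullary difference (CMD)** — per subject, the ISOM mean
  minus the cortex mean. Healthy kidneys have a pronounced T1 CMD; diffuse
  parenchymal disease erodes it.
* **Whole-kidney ADC histogram heterogeneity.** Rejecting grafts show patches
  of raised and lowered diffusivity side by side, so even when the mean ADC
  barely moves, dispersion metrics (SD, interquartile range, entropy of the
  kernel density estimate) separate rejecting from non-rejecting grafts.

`renomap` implements this analysis end to end and, because real animal data
of this kind are generally not shared, ships a digital kidney phantom that
reproduces the study design: layered elliptical cortex/OSOM/ISOM geometry,
per-group tissue parameter sets (healthy controls, isogenic grafts without
rejection, allogenic grafts with chronic rejection at 3 and 6 weeks), a
calibrated two-class patchy ADC heterogeneity field for allografts, and
forward simulation of the three acquisitions with Rician magnitude noise:

* inversion recovery (13 inversion times, 30–8000 ms, TR 18000 ms):
  `S(TI) = |M0 (1 − 2 e^(−TI/T1) + e^(−TR/T1))|`
* multi-echo spin echo (7 echoes, TE 11–77 ms): `S(TE) = M0 e^(−TE/T2)`
* diffusion weighting (7 b-values, 0–800 s/mm²): `S(b) = S0 e^(−b·ADC)`

Voxel-wise fitting uses a deterministic variable-projection search with
polarity restoration for magnitude inversion-recovery T1, and weighted
log-linear least squares (squared-signal weights, optional nonlinear
refinement) for T2 and ADC. Group statistics mirror the standard reporting
layer: Shapiro–Wilk normality checks, one-way ANOVA with Tukey HSD post hoc
tests, unpaired/paired t-tests, and mean ± SEM tables with significance
flags.

## Worked example

Simulate a reduced three-arm study (4 subjects per arm, 64×64 phantoms,
compact sub-ROIs for the relaxometry fits) and look at the group summaries:

```r
library(renomap)
library(dplyr)

cfg <- study_config(
  cohorts = tibble::tibble(group = c("control", "isogenic", "allogenic"),
                           timepoint = c("none", "w3", "w3"),
                           n = c(4L, 4L, 4L)),
  shape = c(64, 64), roi_voxels = 150)
res <- run_study(cfg, seed = 1)

glance(res) |> filter(map_kind == "T1_ms", region %in% c("cortex", "isom"))
#> # A tibble: 6 × 7
#>   group     timepoint map_kind region     n  mean   sem
#>   <chr>     <chr>     <chr>    <chr>  <int> <dbl> <dbl>
#> 1 allogenic w3        T1_ms    cortex     4 1965.  2.44
#> 2 allogenic w3        T1_ms    isom       4 2293.  1.81
#> 3 control   none      T1_ms    cortex     4 1303.  1.44
#> 4 control   none      T1_ms    isom       4 1817.  1.47
#> 5 isogenic  w3        T1_ms    cortex     4 1458.  1.03
#> 6 isogenic  w3        T1_ms    isom       4 1907.  2.32
```

Cortical T1 is recovered near its generation values: ~1300 ms in controls,
mildly raised (~1460 ms) after isogenic transplantation and strongly raised
(~1965 ms) under chronic rejection, with the T1 CMD (ISOM − cortex)
collapsing from ~510 ms to ~330 ms in allografts. The whole-kidney ADC
histogram separates the graft types by dispersion, not by mean:

```r
res$histogram_stats |>
  group_by(group) |>
  summarise(sd = mean(sd), iqr = mean(iqr), entropy = mean(entropy))
#> # A tibble: 3 × 4
#>   group         sd   iqr entropy
#>   <chr>      <dbl> <dbl>   <dbl>
#> 1 allogenic 0.331  0.449   0.809
#> 2 control   0.0932 0.127   0.548
#> 3 isogenic  0.0964 0.145   0.553

res$comparisons |> filter(metric == "hist.sd") |>
  select(test, comparison, p_value, mark)
#> # A tibble: 1 × 4
#>   test       comparison          p_value mark
#>   <chr>      <chr>                 <dbl> <chr>
#> 1 t_unpaired isogenic-allogenic 8.31e-12 ***
```

SD and IQR are in 10⁻³ mm²/s; entropy is the normalized KDE entropy in
[0, 1]. Individual stages are available as plain functions
(`make_phantom()`, `synthesize_subject()`, `fit_t1_ir()`, `fit_t2()`,
`fit_adc()`, `region_means()`, `cmd_table()`, `histogram_metrics()`,
`compare_groups()`), all returning tibbles or light S3 objects with
`tidy()`/`glance()`/`autoplot()` methods, and everything can be written and
read as NIfTI + JSON sidecars (`write_phantom()`, `write_series()`,
`write_param_map()`).

See the methods vignette (`vignettes/quantitative-renal-mri.Rmd`) for the
models, calibration choices and known limitations.

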