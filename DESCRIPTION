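Package: renomap
Title: Quantitative Renal MRI Simulation, Parameter Mapping and Histogram Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital kidney phantoms and an end-to-end quantitative renal MRI
    analysis pipeline for rodent kidney-transplant imaging studies. Generates
    layered cortex/outer-medulla phantoms with optional patchy diffusion
    heterogeneity, forward-simulates inversion-recovery T1, multi-echo T2 and
    diffusion-weighted acquisitions with Rician magnitude noise, fits voxel-wise
    T1/T2/ADC parameter maps (magnitude inversion-recovery fitting with polarity
    restoration, weighted log-linear exponential fits), computes compartmental
    region statistics with the cortico-medullary difference, kernel-density ADC
    histogram heterogeneity metrics (SD, kurtosis, skewness, entropy, IQR), and
    the group-level statistical reporting layer (Shapiro-Wilk, one-way ANOVA with
    Tukey post hoc tests, unpaired and paired t-tests, mean +/- SEM tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
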