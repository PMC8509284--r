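test_that("label map builds ordered concentric compartments", {
  lab <- make_label_map(c(128, 128))
  counts <- table(factor(unclass(lab), levels = 0:3))
  expect_true(all(counts[c("1", "2", "3")] >= 100))
  expect_gt(counts[["1"]], counts[["2"]])
  expect_gt(counts[["2"]], 0)

  # cortex outermost, ISOM innermost: mean distance from center decreases
  # with compartment code
  ctr <- (dim(lab) + 1) / 2
  mean_r <- vapply(1:3, function(code) {
    idx <- which(unclass(lab) == code, arr.ind = TRUE)
    mean(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))

  # whole kidney is a single connected blob: every tissue voxel has a
  # tissue 4-neighbour
  wk <- region_mask(lab, "whole_kidney")
  nb <- rbind(FALSE, wk[-nrow(wk), ]) | rbind(wk[-1, ], FALSE) |
    cbind(FALSE, wk[, -ncol(wk)]) | cbind(wk[, -1], FALSE)
  expect_true(all(nb[wk]))
})

test_that("label map is deterministic and rejects bad inputs", {
  expect_identical(make_label_map(c(96, 96)), make_label_map(c(96, 96)))
  expect_error(make_label_map(c(32, 32)), ">= 64")
  expect_error(make_label_map(c(128, 128),
                              kidney_geometry(r_osom = 0.55, r_isom = 0.55)),
               "Degenerate")
  expect_error(make_label_map(c(128, 128), kidney_geometry(r_isom = 0)),
               "Degenerate")
})

test_that("mixture calibration matches closed forms and Monte Carlo", {
  # SD of a balanced two-class mixture: sqrt(delta^2 + sigma^2)
  expect_equal(mixture_sd(0.315, 0.10), 0.3304921, tolerance = 1e-6)
  expect_equal(calibrate_heterogeneity(0.33, 0.10), 0.3144837,
               tolerance = 1e-6)
  expect_error(calibrate_heterogeneity(0.10, 0.33), "exceed")

  # IQR by CDF inversion agrees with a frozen 1e6-draw Monte-Carlo value
  expect_equal(mixture_iqr(0.315, 0.10), 0.62974, tolerance = 0.005)

  # joint SD+IQR calibration reproduces both targets
  cal <- calibrate_mixture(0.33, 0.45)
  expect_equal(mixture_sd(cal[["adc_delta"]], cal[["within_patch_sd"]]),
               0.33, tolerance = 1e-6)
  expect_equal(mixture_iqr(cal[["adc_delta"]], cal[["within_patch_sd"]]),
               0.45, tolerance = 1e-6)

  # an IQR/SD ratio at or below the Gaussian 1.349 degenerates to delta = 0
  cal6 <- calibrate_mixture(0.32, 0.43)
  expect_equal(cal6[["adc_delta"]], 0)
  expect_equal(cal6[["within_patch_sd"]], 0.32)
})

test_that("heterogeneity field honours the degenerate and calibrated cases", {
  lab <- make_label_map(small_shape)
  base <- list(cortex = 1.47, osom = 1.47, isom = 1.47)
  degenerate <- list(enabled = TRUE, adc_delta = 0, within_patch_sd = 0,
                     patch_scale_vox = 4)
  f <- make_heterogeneity_field(lab, base, degenerate, seed = 3)
  tissue <- region_mask(lab, "whole_kidney")
  expect_true(all(f[tissue] == 1.47))
  expect_true(all(f[!tissue] == 0))

  expect_error(make_heterogeneity_field(
    lab, base, list(enabled = TRUE, adc_delta = -1, within_patch_sd = 0,
                    patch_scale_vox = 4), seed = 1), "non-negative")
  expect_error(make_heterogeneity_field(
    lab, base, list(enabled = FALSE), seed = 1), "enabled")

  # same seed, same args: bit-identical
  settings <- list(enabled = TRUE, adc_delta = 0.3, within_patch_sd = 0.1,
                   patch_scale_vox = 4)
  expect_identical(make_heterogeneity_field(lab, base, settings, seed = 7),
                   make_heterogeneity_field(lab, base, settings, seed = 7))
})

test_that("phantom truth grids carry the compartment parameters exactly", {
  ph <- control_phantom(c(128, 128))
  lab <- ph$label_map
  expect_equal(mean(ph$truth_t1[region_mask(lab, "cortex")]), 1304)
  expect_equal(mean(ph$truth_t1[region_mask(lab, "isom")]), 1808)
  expect_equal(mean(ph$truth_t2[region_mask(lab, "osom")]), 42)
  expect_equal(mean(ph$truth_adc[region_mask(lab, "om")]), 1.72)
  # compartment purity: piecewise-constant truth on every tissue voxel
  expect_true(all(ph$truth_adc[region_mask(lab, "cortex")] == 1.61))
  expect_true(all(ph$truth_adc[region_mask(lab, "om")] == 1.72))
  expect_true(all(ph$truth_t1[region_mask(lab, "background")] == 0))

  iso <- make_phantom(tissue_parameters("isogenic", "w3"), small_shape, 2)
  wk <- region_mask(iso$label_map, "whole_kidney")
  vals <- iso$truth_adc[wk]
  expect_true(all(vals %in% c(1.29, 1.43)))

  # allograft w3 truth ADC dispersion close to the calibrated 0.33
  allo <- allograft_phantom(c(128, 128), seed = 11)
  wk <- region_mask(allo$label_map, "whole_kidney")
  expect_equal(sd(allo$truth_adc[wk]), 0.33, tolerance = 0.03)

  # reproducibility of the full phantom
  expect_identical(allograft_phantom(seed = 5), allograft_phantom(seed = 5))
})

test_that("tissue parameter sets are validated", {
  expect_error(tissue_parameters("isogenic", "none"), "timepoint")
  p <- tissue_parameters("control")
  p$values$t2_ms[1] <- 2000
  expect_error(make_phantom(p, small_shape), "t1_ms must exceed")
  p <- tissue_parameters("isogenic", "w3")
  p$heterogeneity$enabled <- TRUE
  expect_error(make_phantom(p, small_shape), "allogenic")
})
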