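# Helper: stack n_copies of a single decay curve into a series for
# Monte-Carlo style fitting of many iid voxels at once.
curve_series <- function(kind, curve, axis, n_copies, tr_ms = NA_real_) {
  nx <- 50
  ny <- ceiling(n_copies / nx)
  data <- array(rep(curve, each = nx * ny), c(nx, ny, 1, length(axis)))
  acq_series(kind, data, axis, tr_ms = tr_ms)
}

test_that("noiseless fits recover the phantom truth to 1e-6 relative", {
  for (ph in list(control_phantom(), allograft_phantom(seed = 2))) {
    ser <- synthesize_subject(ph, noiseless_protocol(), seed = 1)
    tissue <- region_mask(ph$label_map, "whole_kidney")
    t1 <- fit_t1_ir(ser$ir)
    expect_true(all(t1$mask[tissue]))
    expect_lt(rel_err(t1$values, ph$truth_t1, tissue), 1e-6)
    t2 <- fit_t2(ser$me)
    expect_lt(rel_err(t2$values, ph$truth_t2, tissue), 1e-6)
    adc <- fit_adc(ser$dwi)
    expect_lt(rel_err(adc$values, ph$truth_adc, tissue), 1e-6)
    # R^2 is 1 on noiseless voxels
    expect_gt(min(t1$quality[tissue]), 1 - 1e-9)
  }
})

test_that("T1 fitting at SNR 40 matches the frozen Monte-Carlo oracle", {
  # oracle (independent signed-data nls, 2000 curves): bias -0.11 %,
  # per-voxel sd 36.3 ms at T1 = 1304; sd 53.7 ms at T1 = 1808
  ti <- default_protocol()$ti_ms
  for (cse in list(list(t1 = 1304, sd = 36.3), list(t1 = 1808, sd = 53.7))) {
    clean <- signal_ir(cse$t1, ti, 18000)
    ser <- curve_series("IR_T1", clean, ti, n_copies = 2500, tr_ms = 18000)
    noisy <- add_rician_noise(ser, snr = 40, seed = 101)
    map <- fit_t1_ir(noisy)
    est <- map$values[map$mask]
    expect_gt(length(est), 2000)
    expect_lt(abs(mean(est) - cse$t1) / cse$t1, 0.005)
    expect_equal(sd(est), cse$sd, tolerance = 0.12)
  }
})

test_that("T1 fit masks degenerate voxels instead of failing", {
  ti <- default_protocol()$ti_ms
  data <- array(0, c(64, 64, 1, length(ti)))
  # one valid voxel among zeros
  data[10, 10, 1, ] <- signal_ir(1304, ti, 18000)
  ser <- acq_series("IR_T1", data, ti, tr_ms = 18000)
  map <- fit_t1_ir(ser)
  expect_true(map$mask[10, 10])
  expect_equal(sum(map$mask), 1)
  short <- acq_series("IR_T1", data[, , , 1:3, drop = FALSE], ti[1:3],
                      tr_ms = 18000)
  expect_error(fit_t1_ir(short), "4 inversion times")
})

test_that("T2 fitting is exact noiseless and within 1 ms at SNR 40", {
  te <- seq(11, 77, 11)
  ser <- curve_series("ME_T2", signal_t2(42, te), te, 100)
  map <- fit_t2(ser)
  expect_equal(map$values[map$mask], rep(42, sum(map$mask)),
               tolerance = 1e-9)

  # constant signal (T2 -> infinity): clipped at the 500 ms bound and masked
  const <- acq_series("ME_T2", array(1, c(64, 64, 1, 7)), te)
  cm <- fit_t2(const)
  expect_true(all(cm$values[is.finite(cm$values)] <= 500))
  expect_false(any(cm$mask))

  # group-mean recovery at SNR 40 (oracle: mean 54.58, sd 3.0)
  noisy <- add_rician_noise(curve_series("ME_T2", signal_t2(54, te), te,
                                         1500), 40, seed = 11)
  nm <- fit_t2(noisy)
  expect_lt(abs(mean(nm$values[nm$mask]) - 54), 1)
})

test_that("ADC fitting is exact noiseless and flags pathological voxels", {
  b <- default_protocol()$b_s_mm2
  ser <- curve_series("DWI", signal_dwi(1.72, b), b, 100)
  map <- fit_adc(ser)
  expect_equal(map$values[map$mask], rep(1.72, sum(map$mask)),
               tolerance = 1e-9)

  # zero-diffusion voxel: fitted ~0 but excluded by the minimum-ADC QC bound
  flat <- acq_series("DWI", array(1, c(64, 64, 1, length(b))), b)
  fm <- fit_adc(flat)
  expect_true(all(abs(fm$values[is.finite(fm$values)]) < 0.05 + 1e-9))
  expect_false(any(fm$mask))

  expect_error(fit_adc(acq_series("DWI", array(1, c(64, 64, 1, 2)),
                                  c(100, 800))), "b = 0")
})

test_that("log-linear and NLS exponential fits agree on noiseless data", {
  ph <- control_phantom()
  ser <- synthesize_subject(ph, noiseless_protocol(), seed = 1)
  tissue <- region_mask(ph$label_map, "whole_kidney")
  a1 <- fit_adc(ser$dwi)
  a2 <- fit_adc(ser$dwi, options = fit_options(refine = "nls"))
  expect_lt(max(abs(a1$values[tissue] - a2$values[tissue])), 1e-10)
  t1 <- fit_t2(ser$me)
  t2 <- fit_t2(ser$me, options = fit_options(refine = "nls"))
  expect_lt(max(abs(t1$values[tissue] - t2$values[tissue])), 1e-10)
})

test_that("masked voxels always carry finite in-bounds values", {
  ph <- allograft_phantom(seed = 9)
  ser <- synthesize_subject(ph, default_protocol(snr = 15), seed = 9)
  opts <- fit_options()
  t1 <- fit_t1_ir(ser$ir)
  expect_true(all(is.finite(t1$values[t1$mask])))
  expect_true(all(t1$values[t1$mask] > opts$t1_bounds[1] &
                    t1$values[t1$mask] < opts$t1_bounds[2]))
  expect_true(all(t1$quality[t1$mask] >= opts$r2_floor))
  adc <- fit_adc(ser$dwi)
  expect_true(all(adc$values[adc$mask] > opts$adc_bounds[1] &
                    adc$values[adc$mask] < opts$adc_bounds[2]))
  t2 <- fit_t2(ser$me)
  expect_true(all(t2$values[t2$mask] > opts$t2_bounds[1] &
                    t2$values[t2$mask] < opts$t2_bounds[2]))
})
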