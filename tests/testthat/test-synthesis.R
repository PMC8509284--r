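test_that("inversion-recovery signal model obeys its closed forms", {
  # long-TI limit with full relaxation
  expect_equal(signal_ir(1304, ti_ms = 1e9, tr_ms = 1e9), 1, tolerance = 1e-9)
  # null point at TI = T1 ln 2 for an ideal pulse and infinite TR
  expect_equal(signal_ir(1304, ti_ms = 1304 * log(2), tr_ms = 1e12), 0,
               tolerance = 1e-9)
  # frozen arithmetic check at the protocol TR
  expect_equal(signal_ir(1304, ti_ms = 1000, tr_ms = 18000), 0.0710729554,
               tolerance = 1e-8)
  # reduced inversion efficiency shifts the null
  expect_gt(signal_ir(1304, 1304 * log(2), 1e12, inv_eff = 0.8), 0.05)
  expect_error(signal_ir(-5, 100), "positive")
  expect_error(signal_ir(1304, 100, inv_eff = 1.2), "inv_eff")
})

test_that("T2 and DWI signal models decay mono-exponentially", {
  expect_equal(signal_t2(42, 0), 1)
  expect_equal(signal_t2(42, 42), exp(-1))
  s <- signal_t2(42, seq(11, 77, 11))
  expect_length(s, 7)
  expect_true(all(diff(s) < 0))

  expect_equal(signal_dwi(1.72, 0), 1)
  expect_equal(signal_dwi(1.72, 800), exp(-1.376))
  expect_equal(signal_dwi(0, c(0, 400, 800)), c(1, 1, 1))
  expect_error(signal_t2(-1, 10), "positive")
})

test_that("Rician noise has the magnitude-image moments", {
  ph <- control_phantom()
  ser <- synthesize_subject(ph, noiseless_protocol(), seed = 1)$dwi

  # infinite SNR leaves the data untouched
  expect_identical(add_rician_noise(ser, Inf, seed = 1)$data, ser$data)
  expect_error(add_rician_noise(ser, -2, seed = 1), "positive")

  # zero-signal voxels follow a Rayleigh law with mean sigma*sqrt(pi/2)
  zero <- acq_series("DWI", array(0, c(100, 100, 1, 2)), c(0, 800))
  noisy <- add_rician_noise(zero, snr = 10, seed = 42)
  expect_equal(mean(noisy$data), 0.1 * sqrt(pi / 2), tolerance = 0.01)

  # high-SNR second-moment approximation: E|s+n| ~ sqrt(s^2 + 2 sigma^2)
  s0 <- acq_series("DWI", array(1, c(200, 200, 1, 2)), c(0, 800))
  noisy <- add_rician_noise(s0, snr = 40, seed = 7)
  expect_equal(mean(noisy$data), sqrt(1 + 2 / 40^2), tolerance = 1e-3)

  # reproducible given the seed
  expect_identical(add_rician_noise(ser, 40, seed = 9)$data,
                   add_rician_noise(ser, 40, seed = 9)$data)
})

test_that("noiseless synthesis reproduces the closed forms voxel-wise", {
  ph <- control_phantom()
  ser <- synthesize_subject(ph, noiseless_protocol(), seed = 1)
  idx <- which(region_mask(ph$label_map, "isom"), arr.ind = TRUE)[1, ]
  t1 <- ph$truth_t1[idx[1], idx[2]]
  expect_equal(ser$ir$data[idx[1], idx[2], 1, ],
               signal_ir(t1, ser$ir$param_axis, 18000), tolerance = 1e-12)
  t2 <- ph$truth_t2[idx[1], idx[2]]
  expect_equal(ser$me$data[idx[1], idx[2], 1, ],
               signal_t2(t2, ser$me$param_axis), tolerance = 1e-12)
  adc <- ph$truth_adc[idx[1], idx[2]]
  expect_equal(ser$dwi$data[idx[1], idx[2], 1, ],
               signal_dwi(adc, ser$dwi$param_axis), tolerance = 1e-12)
  # background voxels carry no clean signal
  expect_true(all(ser$ir$data[1, 1, 1, ] == 0))

  # default protocol carries the printed acquisition axes
  p <- default_protocol()
  expect_identical(p$ti_ms, c(30, 100, 200, 300, 500, 700, 1000, 1200, 1500,
                              2000, 3000, 5000, 8000))
  expect_identical(p$te_ms, seq(11, 77, by = 11))
  expect_identical(p$b_s_mm2, c(0, 100, 200, 300, 400, 600, 800))
  expect_identical(p$tr_ms, 18000)

  # noisy synthesis is reproducible given the subject seed
  a <- synthesize_subject(ph, default_protocol(), seed = 3)
  b <- synthesize_subject(ph, default_protocol(), seed = 3)
  expect_identical(a$ir$data, b$ir$data)
  expect_identical(a$dwi$data, b$dwi$data)
})

test_that("acquisition series validates its contract", {
  expect_error(acq_series("DWI", array(1, c(4, 4, 1, 3)), c(0, 800)),
               "param_axis")
  expect_error(acq_series("DWI", array(1, c(4, 4, 1, 2)), c(800, 0)),
               "increasing")
  expect_error(acq_series("DWI", array(-1, c(4, 4, 1, 2)), c(0, 800)),
               "non-negative")
})
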