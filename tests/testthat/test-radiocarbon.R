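test_that("composite constant multiplies out the correction factors", {
  expect_identical(composite_constant(), 13.356)
  expect_identical(composite_constant(production_constants(12, 1.0, 1.0)), 12.0)
  expect_identical(composite_constant(production_constants(12, 1.05, 1.0)), 12.6)
})

test_that("mean excess activity handles replicates and sign", {
  expect_equal(mean_dpm_excess(1000, 100), 900)
  expect_equal(mean_dpm_excess(c(1000, 1200), c(100, 100)), 1000)
  expect_equal(mean_dpm_excess(90, 100), -10)
  # unequal replicate counts: difference of means
  expect_equal(mean_dpm_excess(c(1000, 1200, 1100), c(100, 200)), 1100 - 150)
  expect_error(mean_dpm_excess(numeric(0), 100), "empty")
})

test_that("total CO2 guards its input domain", {
  expect_error(total_co2(5, 0, 8.1), "alkalinity undefined")
  expect_error(total_co2(5, 34, 5.5), "pH out of carbonate-routine range")
  expect_error(total_co2(5, 34, 9.5), "pH out of carbonate-routine range")
})

test_that("total CO2 at (5 degC, S 34, pH 8.1) matches the independent solver", {
  got <- total_co2(5, 34, 8.1)
  expect_gt(got$total_co2_mM, 2.0)
  expect_lt(got$total_co2_mM, 2.3)
  ref <- oracle_total_co2(5, 34, 8.1)
  expect_lt(abs(got$total_co2_mM - ref) / ref, 0.05)
})

test_that("total CO2 is strictly increasing in salinity at fixed T, pH", {
  s <- seq(28, 35, by = 0.5)
  dic <- total_co2(4, s, 8.1)$total_co2_mM
  expect_true(all(diff(dic) > 0))
})

test_that("total CO2 approaches half the alkalinity as pH rises", {
  # h -> 0 turns all carbonate alkalinity into carbonate ion: DIC -> CA / 2
  ph <- seq(7.8, 9.0, by = 0.2)
  out <- total_co2(4, 34, ph)
  ratio <- out$total_co2_mM / out$carbonate_alkalinity_meq_l
  expect_true(all(diff(ratio) < 0))
  expect_true(all(ratio > 0.5))
  # by pH 9 most alkalinity is carbonate ion: ratio 0.756 at (4 degC, S 34)
  expect_equal(ratio[length(ratio)], 0.756, tolerance = 5e-3)
})

test_that("compute_pe reproduces hand arithmetic and the k2 convention", {
  # 1000 dpm excess, 2.0 mM DIC, k2 = 0.5 (two-hour exposure), 8 uCi tracer
  res <- compute_pe(1000, 0, dpm_added = 1.776e7, total_co2_mM = 2.0,
                    exposure_hours = 2)
  expect_equal(res$k2, 0.5)
  expect_equal(res$pe_mgC_m3_h, 1000 * 2.0 * 13.356 * 0.5 * 1e3 / 1.776e7,
               tolerance = 1e-12)
  expect_equal(res$pe_mgC_m3_h, 0.752, tolerance = 1e-3)

  # tracer given in microcuries takes the 2.22e6 dpm/uCi conversion
  res_uci <- compute_pe(1000, 0, dpm_added = 8, total_co2_mM = 2.0,
                        exposure_hours = 2, dpm_added_unit = "uCi")
  expect_equal(res_uci$pe_mgC_m3_h, res$pe_mgC_m3_h)
})

test_that("zero excess gives zero production; negatives clamp with a flag", {
  expect_equal(compute_pe(100, 100, 1e7, 2.0)$pe_mgC_m3_h, 0)
  res <- compute_pe(90, 100, 1e7, 2.0)
  expect_equal(res$pe_mgC_m3_h, 0)
  expect_lt(res$pe_raw_mgC_m3_h, 0)
  expect_true(res$pe_clamped)
  expect_error(compute_pe(100, 0, 0, 2.0), "positive")
  expect_error(pe_volumetric(100, NA_real_, 1e7), "carbonate")
})

test_that("production is homogeneous of degree 1 in its linear factors", {
  set.seed(41)
  for (i in 1:50) {
    excess <- stats::runif(1, 10, 1e5)
    dic <- stats::runif(1, 1.5, 2.5)
    added <- stats::runif(1, 1e6, 1e8)
    base <- pe_volumetric(excess, dic, added)$pe_mgC_m3_h
    expect_equal(pe_volumetric(2 * excess, dic, added)$pe_mgC_m3_h, 2 * base)
    expect_equal(pe_volumetric(excess, 2 * dic, added)$pe_mgC_m3_h, 2 * base)
    expect_equal(pe_volumetric(excess, dic, 2 * added)$pe_mgC_m3_h, base / 2)
  }
})
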