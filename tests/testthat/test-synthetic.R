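test_that("zero-noise casts round-trip exactly through the pipeline", {
  scs <- default_campaign_scenarios(n_casts = 1, noise_cv = 0)
  for (sc in scs[c("Hornsund_Glacier", "Kongsfjorden_Outer")]) {
    set.seed(91)
    g <- generate_cast(sc, "rt")
    lv <- process_casts(g$cast)
    expect_equal(lv$pe_mgC_m3_h, g$truth$pe_true$pe_mgC_m3_h,
                 tolerance = 1e-10)
    expect_equal(lv$chl_mgm3, g$truth$pe_true$chl_mgm3, tolerance = 1e-10)
  }
})

test_that("fixed seeds give bit-identical casts; distinct seeds differ", {
  sc <- default_campaign_scenarios(n_casts = 1, noise_cv = 0.1)$Hornsund_Inner
  set.seed(92); a <- generate_cast(sc, "x")
  set.seed(92); b <- generate_cast(sc, "x")
  expect_identical(a, b)
  set.seed(93); c <- generate_cast(sc, "x")
  expect_false(identical(a$cast$dpm_light_mean, c$cast$dpm_light_mean))
})

test_that("turbid glacier water extinguishes production by 10 m", {
  sc <- default_campaign_scenarios(n_casts = 1)$Kongsfjorden_Glacier
  expect_equal(sc$kd_per_m, 0.8)
  tr <- scenario_truth(sc, c(0, 10))
  expect_lt(tr$pe_mgC_m3_h[2], 0.01 * tr$pe_mgC_m3_h[1])
})

test_that("scenario validation catches inconsistencies", {
  sc <- default_campaign_scenarios(n_casts = 1)$Hornsund_Glacier
  args <- unclass(sc)
  args$chl_max_depth_m <- 80   # beyond the deepest sampled level
  expect_error(do.call(zone_scenario, args), "inconsistent scenario")
  expect_error(generate_campaign(list(sc, sc)), "duplicate")
})

test_that("campaign substreams are reproducible and zone-structured", {
  scs <- default_campaign_scenarios(n_casts = 4, noise_cv = 0.05)
  c1 <- generate_campaign(scs, seed = 7)
  c2 <- generate_campaign(scs, seed = 7)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$casts), 6 * 4 * 10)
  expect_equal(nrow(c1$truth), 24)

  # production maximum deepens seaward in the Kongsfjorden strata
  lv <- process_casts(c1$casts)
  k <- lv[lv$fjord == "Kongsfjorden", ]
  env_argmax <- vapply(c("Glacier", "Inner", "Outer"), function(zn) {
    zz <- k[k$zone == zn, ]
    env <- profile_envelope(zz, grid = scs[[1]]$depths,
                            value_col = "pe_mgC_m3_h")
    env$depth_m[which.max(env$median)]
  }, numeric(1))
  expect_true(all(diff(env_argmax) > 0))
})

test_that("degenerate single-cast strata summarize with singleton flags", {
  scs <- default_campaign_scenarios(n_casts = 1, noise_cv = 0.05)
  camp <- generate_campaign(scs["Hornsund_Outer"], seed = 3)
  res <- run_pipeline(camp$casts)
  expect_true(all(res$zone_pe0$singleton))
  expect_equal(res$zone_pe0$sd, 0)
  expect_null(res$comparisons$Hornsund)
})

test_that("hidden truth is internally consistent", {
  sc <- default_campaign_scenarios(n_casts = 1)$Kongsfjorden_Outer
  set.seed(94)
  g <- generate_cast(sc, "t")
  # truth depth-of-max equals the argmax of the true profile on the grid
  expect_equal(g$truth$z_max_pe_true,
               depth_of_maximum(g$truth$pe_true$depth_m,
                                g$truth$pe_true$pe_mgC_m3_h))
  # true Pi equals fine quadrature of the closed form over 0-30 m
  fine <- stats::integrate(function(z) scenario_truth(sc, z)$pe_mgC_m3_h,
                           0, 30)$value * 24
  expect_equal(g$truth$pi_true_mgC_m2_day, fine, tolerance = 1e-6)
})
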