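test_that("zone summary computes range, mean and sample SD", {
  s <- summarize_zone(c(1, 2, 3), fjord = "Hornsund", zone = "Glacier",
                      variable = "pe0")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)   # n - 1 denominator
  expect_equal(c(s$min, s$max, s$n), c(1, 3, 3))

  single <- summarize_zone(2.0)
  expect_equal(c(single$min, single$max, single$mean, single$sd),
               c(2, 2, 2, 0))
  expect_true(single$singleton)
  expect_error(summarize_zone(numeric(0)), "no values")
})

test_that("fold ratio rounds by convention and respects identities", {
  expect_equal(fold_ratio(6.0, 2.18)$ratio, 2.8)
  expect_equal(fold_ratio(740.4, 111.5, "nearest_half")$ratio, 6.5)
  expect_equal(fold_ratio(5, 5)$ratio, 1.0)
  s <- summarize_zone(c(1, 2, 3))
  expect_equal(fold_ratio(s, s)$ratio, 1.0)
  expect_error(fold_ratio(5, 0), "positive")
  # antitone in the denominator mean
  set.seed(71)
  for (i in 1:20) {
    a <- stats::runif(1, 1, 10)
    b1 <- stats::runif(1, 0.5, 5)
    b2 <- b1 + stats::runif(1, 0.1, 2)
    expect_gt(fold_ratio(a, b1)$ratio_raw, fold_ratio(a, b2)$ratio_raw)
  }
})

test_that("null normal groups take the ANOVA branch with p near 1 when identical", {
  set.seed(81)
  g <- stats::rnorm(60)
  res <- compare_zones(list(a = g, b = g + 1e-9, c = g - 1e-9))
  expect_identical(res$test_used, "ANOVA")
  expect_gt(res$p_value, 0.99)
  expect_true(all(res$normality_p > 0.05))
})

test_that("a strongly log-normal group forces the rank-based branch", {
  set.seed(82)
  groups <- list(a = stats::rnorm(40), b = stats::rnorm(40),
                 c = exp(stats::rnorm(40, sd = 2)))
  res <- compare_zones(groups)
  expect_identical(res$test_used, "KruskalWallis")
  expect_lt(min(res$normality_p), 0.05)
})

test_that("comparison is deterministic and validates group sizes", {
  set.seed(83)
  groups <- list(a = stats::rnorm(10), b = stats::rnorm(10),
                 c = stats::rnorm(10))
  r1 <- compare_zones(groups)
  r2 <- compare_zones(groups)
  expect_identical(r1, r2)
  expect_error(compare_zones(list(a = stats::rnorm(10), b = c(1, 2))),
               "too small.*b")
  expect_error(compare_zones(list(a = stats::rnorm(10))))
})

test_that("branch decision is pure in the two gate p-values", {
  set.seed(84)
  groups <- list(a = stats::rnorm(20), b = stats::rnorm(20),
                 c = stats::rnorm(20))
  res <- compare_zones(groups, alpha = 0.05)
  gate_pass <- all(res$normality_p > 0.05) &&
    res$variance_homogeneity_p > 0.05
  expect_identical(res$test_used,
                   if (gate_pass) "ANOVA" else "KruskalWallis")
})

test_that("surface production simulated at the calibrated mean recovers it", {
  sc <- default_campaign_scenarios(n_casts = 40, noise_cv = 0.05)$Hornsund_Glacier
  set.seed(85)
  pe0 <- vapply(1:40, function(j) {
    g <- generate_cast(sc, sprintf("h%02d", j))
    lv <- process_casts(g$cast)
    surface_value(lv$depth_m, lv$pe_mgC_m3_h)$value
  }, numeric(1))
  s <- summarize_zone(pe0)
  se <- s$sd / sqrt(s$n)
  expect_lt(abs(s$mean - 6.0), 2 * se + 1e-8)
})
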