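test_that("surface value is exact extraction when 0 m was sampled", {
  sv <- surface_value(c(0, 3), c(2.18, 5.0))
  expect_identical(sv$value, 2.18)
  expect_false(sv$substituted)

  sv <- surface_value(c(0, 3, 7), c(6.0, 20.7, 0.4))
  expect_identical(sv$value, 6.0)
  expect_identical(sv$depth_m, 0)
})

test_that("surface value substitutes the shallowest sample, flagged", {
  sv <- surface_value(c(1, 5), c(4.0, 1.0))
  expect_identical(sv$value, 4.0)
  expect_true(sv$substituted)
  expect_identical(sv$depth_m, 1)
})

test_that("surface value rejects an empty series", {
  expect_error(surface_value(numeric(0), numeric(0)), "no levels")
})

test_that("depth of maximum finds the peak, breaking ties shallow", {
  expect_identical(depth_of_maximum(c(0, 3, 7), c(1, 9, 2)), 3)
  expect_identical(depth_of_maximum(c(0, 3, 7), c(5, 5, 1)), 0)
  expect_error(depth_of_maximum(c(0, 3), c(NA_real_, NA_real_)), "missing")
})

test_that("depth of maximum is invariant under positive rescaling", {
  set.seed(11)
  for (i in 1:25) {
    d <- sort(sample(0:50, 8))
    v <- stats::runif(8)
    k <- stats::runif(1, 0.01, 100)
    expect_identical(depth_of_maximum(d, v), depth_of_maximum(d, k * v))
  }
})

make_profiles <- function(values_by_cast, depths = c(0, 5, 10, 20)) {
  dplyr::bind_rows(lapply(names(values_by_cast), function(id) {
    tibble::tibble(cast_id = id, depth_m = depths,
                   value = values_by_cast[[id]])
  }))
}

test_that("single-cast envelope collapses to the interpolated cast", {
  p <- make_profiles(list(a = c(1, 4, 2, 0)))
  env <- profile_envelope(p, grid = c(0, 2.5, 5, 10), value_col = "value")
  expect_equal(env$median, env$min)
  expect_equal(env$median, env$max)
  expect_equal(env$median[2], 2.5)  # linear between 1 and 4
  expect_equal(env$n_casts, rep(1L, 4))
})

test_that("constant casts give median/min/max at the constants", {
  p <- make_profiles(list(a = rep(1, 4), b = rep(2, 4), c = rep(3, 4)))
  env <- profile_envelope(p, grid = c(0, 5, 10), value_col = "value")
  expect_equal(env$median, rep(2, 3))
  expect_equal(env$min, rep(1, 3))
  expect_equal(env$max, rep(3, 3))
})

test_that("min <= median <= max pointwise on random batches", {
  set.seed(21)
  for (i in 1:10) {
    vals <- setNames(lapply(1:5, function(j) stats::rlnorm(4)),
                     paste0("c", 1:5))
    env <- profile_envelope(make_profiles(vals), grid = c(0, 3, 8, 15),
                            value_col = "value")
    expect_true(all(env$min <= env$median + 1e-12))
    expect_true(all(env$median <= env$max + 1e-12))
  }
})

test_that("envelope excludes casts outside their sampled span, with counts", {
  p <- dplyr::bind_rows(
    tibble::tibble(cast_id = "deep", depth_m = c(0, 10, 30), value = 1),
    tibble::tibble(cast_id = "shallow", depth_m = c(0, 5, 10), value = 3)
  )
  env <- profile_envelope(p, grid = c(0, 10, 20), value_col = "value")
  expect_equal(env$n_casts, c(2L, 2L, 1L))
  expect_equal(env$max[3], 1)  # only the deep cast spans 20 m
  expect_error(profile_envelope(p[0, ], grid = 0, value_col = "value"),
               "empty")
})

test_that("glacier chlorophyll envelope recovers the 7 m peak", {
  scs <- default_campaign_scenarios(n_casts = 50, noise_cv = 0.1)
  sc <- scs$Hornsund_Glacier
  set.seed(31)
  casts <- dplyr::bind_rows(lapply(1:50, function(j) {
    generate_cast(sc, cast_id = sprintf("g%02d", j))$cast
  }))
  lv <- process_casts(casts)
  env <- profile_envelope(lv, grid = sc$depths, value_col = "chl_mgm3")
  peak <- env$depth_m[which.max(env$median)]
  grid_idx <- match(c(peak, 7), sc$depths)
  expect_lte(abs(diff(grid_idx)), 1)  # within one grid step of truth
})
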