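test_that("reshuffle surrogates preserve the exact value multiset", {
  set.seed(12)
  g <- spatial_grid(matrix(rnorm(15 * 11), 15, 11))
  for (i in 1:5) {
    sg <- reshuffle_surrogate(g)
    expect_identical(dim(sg$values), dim(g$values))
    expect_identical(sort(as.vector(sg$values)), sort(as.vector(g$values)))
    m0 <- spatial_moments(g); m1 <- spatial_moments(sg)
    expect_identical(m1$variance, m0$variance)
    expect_identical(m1$skewness, m0$skewness)
  }
})

test_that("gaussian surrogates match mean/variance and refuse occupancy data", {
  set.seed(13)
  g <- spatial_grid(matrix(rgamma(900, 2), 30, 30))
  mus <- replicate(300, mean(gaussian_surrogate(g)$values))
  expect_lt(abs(mean(mus) - mean(g$values)), 4 * sd(mus) / sqrt(300))
  sks <- replicate(300, spatial_moments(gaussian_surrogate(g))$skewness)
  expect_lt(abs(mean(sks)), 4 * sd(sks) / sqrt(300))
  expect_error(gaussian_surrogate(random_occupancy(10, 10)),
               class = "spatialews_error_inapplicable_null")
})

test_that("surrogate ensembles are deterministic under a fixed seed", {
  g <- spatial_grid(matrix(rnorm(100), 10, 10))
  set.seed(77); a <- reshuffle_surrogate(g)$values
  set.seed(77); b <- reshuffle_surrogate(g)$values
  expect_identical(a, b)
  set.seed(78); cb1 <- confidence_band(g, "morans_i", n = 50)
  set.seed(78); cb2 <- confidence_band(g, "morans_i", n = 50)
  expect_identical(cb1, cb2)
})

test_that("variance under the reshuffle null degenerates onto the observed value", {
  set.seed(14)
  g <- spatial_grid(matrix(rnorm(144), 12, 12))
  expect_warning(cb <- confidence_band(g, "variance", n = 50), "degenerate")
  expect_equal(cb$lower, cb$observed)
  expect_equal(cb$upper, cb$observed)
  expect_false(cb$significant)
})

test_that("the gaussian surrogate is rejected as a variance null", {
  g <- spatial_grid(matrix(rnorm(100), 10, 10))
  expect_error(confidence_band(g, "variance", method = "gaussian"),
               class = "spatialews_error_invalid_null")
  expect_s3_class(suppressWarnings(
    confidence_band(g, "variance", method = "gaussian", n = 20,
                    allow_invalid_null = TRUE)), "tbl_df")
})

test_that("clustered occupancy snapshots flag significant spatial correlation", {
  s <- simulate_facilitation_ca(60, driver_values = c(0.9, 0.85),
                                steps_first = 200, steps_next = 50, seed = 3)
  set.seed(15)
  cb <- confidence_band(s$snapshots[[1]], "morans_i", n = 100)
  expect_true(cb$significant)
  expect_gt(cb$observed, cb$upper)
})

test_that("coarse-graining null test calibrates on iid grids and detects structure", {
  set.seed(16)
  g <- spatial_grid(matrix(rnorm(40 * 40), 40, 40))
  res <- coarse_grain_null_test(g, sub = 4, statistic = "variance", n = 100)
  # variance of a mean of sub^2 iid values: sigma^2 / sub^2
  expect_equal(res$observed, 1 / 16, tolerance = 0.3)
  expect_false(res$significant)

  s <- simulate_facilitation_ca(100, driver_values = c(0.75, 0.7),
                                steps_first = 250, steps_next = 50, seed = 4)
  res2 <- coarse_grain_null_test(s$snapshots[[2]], sub = 5,
                                 statistic = "variance", n = 100,
                                 mode = "count")
  expect_true(res2$significant)
  expect_gt(res2$observed, res2$upper)

  expect_warning(coarse_grain_null_test(g, sub = 1, n = 20),
                 "identical to the original")
})

test_that("chi-squared spectral bands have the stated structure and coverage", {
  b <- chi2_spectrum_band(c(4, 12, 20), level = 0.95)
  expect_true(all(b$lower <= b$upper))
  # bands shrink toward 1 (the expected mean multiplier) as counts grow
  expect_lt(b$upper[[3]], b$upper[[1]])
  expect_gt(b$lower[[3]], b$lower[[1]])

  # empirical coverage of ring bands on white noise
  set.seed(17)
  n <- 24
  covered <- 0; total <- 0
  for (rep in 1:150) {
    g <- spatial_grid(matrix(rnorm(n * n), n, n))
    rs <- r_spectrum(periodogram2d(g))
    band <- chi2_spectrum_band(rs$count, level = 0.95, n_cells = n * n)
    sel <- rs$count > 0
    covered <- covered + sum(rs$power[sel] >= band$lower[sel] &
                             rs$power[sel] <= band$upper[sel])
    total <- total + sum(sel)
  }
  expect_gt(covered / total, 0.92)
  expect_lt(covered / total, 0.98)
})

test_that("Moran's I type-I error under the reshuffle null is near nominal", {
  set.seed(99)
  hits <- replicate(400, {
    g <- spatial_grid(matrix(rnorm(144), 12, 12))
    suppressWarnings(confidence_band(g, "morans_i", n = 99)$significant)
  })
  rate <- mean(hits)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.09)
})
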