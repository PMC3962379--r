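test_that("Parseval holds for the unscaled periodogram on arbitrary grids", {
  set.seed(5)
  grids <- list(
    spatial_grid(matrix(rnorm(32 * 32), 32, 32)),
    spatial_grid(matrix(rexp(24 * 40), 24, 40)),
    spatial_grid(outer(1:32, 1:32, function(i, j) sin(i / 2) + cos(j / 3))),
    coarse_grain(random_occupancy(50, 50), 2, "count"))
  for (g in grids) {
    ps <- periodogram2d(g, scale_by_variance = FALSE)
    n <- prod(dim(g$values))
    expect_equal(ps$total_power, n * spatial_moments(g)$variance,
                 tolerance = 1e-12)
  }
  # scaled spectrum totals 1
  expect_equal(periodogram2d(grids[[1]])$total_power, 1, tolerance = 1e-12)
  expect_error(periodogram2d(spatial_grid(matrix(1, 4, 4))),
               class = "spatialews_error_undefined")
})

test_that("a pure cosine concentrates all power at its radial index", {
  g <- spatial_grid(outer(1:64, 1:64, function(i, j) cos(2 * pi * 3 * (i - 1) / 64)),
                    boundary = "periodic")
  rs <- r_spectrum(periodogram2d(g))
  expect_equal(rs$power[[3]], 1, tolerance = 1e-12)
  expect_equal(sum(rs$power[-3]), 0, tolerance = 1e-12)
  # reddening: all power in the lowest rings
  expect_equal(reddening_index(periodogram2d(g), 0.2), 1, tolerance = 1e-12)
})

test_that("radial and angular spectra partition the retained power exactly", {
  set.seed(6)
  for (rep in 1:5) {
    g <- spatial_grid(matrix(rnorm(30 * 30), 30, 30))
    ps <- periodogram2d(g)
    rs <- r_spectrum(ps)
    ts <- theta_spectrum(ps, n_sectors = sample(c(4, 8, 12, 18), 1))
    expect_equal(sum(rs$power) + attr(rs, "discarded_power"), ps$total_power,
                 tolerance = 1e-12)
    expect_equal(sum(ts$power), ps$total_power, tolerance = 1e-12)
  }
})

test_that("rotating the grid 90 degrees shifts sectors and fixes rings", {
  set.seed(7)
  # odd size: no Nyquist ordinates, so the rotation maps sectors cleanly
  vals <- matrix(rnorm(35 * 35), 35, 35)
  rot <- t(vals)[, rev(seq_len(35))]  # 90-degree rotation
  g <- spatial_grid(vals); gr <- spatial_grid(rot)
  ps <- periodogram2d(g); psr <- periodogram2d(gr)
  expect_equal(r_spectrum(psr)$power, r_spectrum(ps)$power, tolerance = 1e-10)
  ts <- theta_spectrum(ps, 12); tsr <- theta_spectrum(psr, 12)
  shift <- 90 / (180 / 12)  # sectors per quarter turn
  expect_equal(tsr$power, ts$power[((seq_len(12) - 1 + shift) %% 12) + 1],
               tolerance = 1e-10)
})

test_that("anisotropic stripes concentrate angular power in one sector", {
  g <- spatial_grid(outer(1:48, 1:48, function(i, j) cos(2 * pi * 5 * (i - 1) / 48)),
                    boundary = "periodic")
  ts <- theta_spectrum(periodogram2d(g), 12)
  # variation along rows (x): all power at angle 0
  expect_equal(ts$power[[1]], 1, tolerance = 1e-12)
  cls <- classify_spectrum(r_spectrum(periodogram2d(g)), ts,
                           spectrum_null_bands(g))
  expect_false(cls$isotropic)
  expect_equal(cls$dominant_angle, 7.5)
})

test_that("white noise is classified aperiodic and isotropic", {
  set.seed(8)
  res <- replicate(30, {
    g <- spatial_grid(matrix(rnorm(48 * 48), 48, 48))
    ps <- periodogram2d(g)
    cls <- classify_spectrum(r_spectrum(ps), theta_spectrum(ps),
                             spectrum_null_bands(g))
    c(cls$periodic, cls$isotropic)
  })
  expect_lte(mean(res[1, ]), 0.1)   # family-wise periodic false positives
  expect_gte(mean(res[2, ]), 0.9)
})

test_that("band binning mismatches are a configuration error", {
  set.seed(9)
  g <- spatial_grid(matrix(rnorm(400), 20, 20))
  ps <- periodogram2d(g)
  nb <- spectrum_null_bands(g)
  expect_error(classify_spectrum(r_spectrum(ps), theta_spectrum(ps, 6), nb),
               class = "spatialews_error_configuration")
})

test_that("analytic chi-squared bands agree with the reshuffle ensemble", {
  set.seed(10)
  g <- spatial_grid(matrix(rnorm(32 * 32), 32, 32))
  b1 <- spectrum_null_bands(g, method = "chi2", adjust = "none")
  b2 <- spectrum_null_bands(g, method = "reshuffle", n_surrogates = 300,
                            adjust = "none")
  # compare on rings with enough ordinates for the ensemble quantiles
  sel <- which(r_spectrum(periodogram2d(g))$count >= 20)
  expect_equal(b1$r$upper[sel], b2$r$upper[sel], tolerance = 0.25)
  expect_equal(b1$r$lower[sel], b2$r$lower[sel], tolerance = 0.25)
})

test_that("white-noise reddening matches the low-wavenumber ordinate share", {
  set.seed(55)
  n <- 64
  idx <- replicate(20, {
    g <- spatial_grid(matrix(rnorm(n * n), n, n))
    reddening_index(periodogram2d(g), 0.2)
  })
  rs <- r_spectrum(periodogram2d(spatial_grid(matrix(rnorm(n * n), n, n))))
  cutoff <- 0.2 * (n %/% 2)
  share <- sum(rs$count[rs$wavenumber <= cutoff]) / (n * n - 1)
  expect_equal(mean(idx), share, tolerance = 0.15)
})
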