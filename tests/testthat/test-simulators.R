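# Simulator behaviour is checked at reduced lattice size; the full-scale
# gradient properties live in the acceptance suite.

test_that("all three simulators are deterministic under a fixed seed", {
  a <- simulate_local_feedback(24, driver_values = c(3, 2.5), relax_first = 10,
                               relax_next = 5, seed = 5)
  b <- simulate_local_feedback(24, driver_values = c(3, 2.5), relax_first = 10,
                               relax_next = 5, seed = 5)
  expect_identical(lapply(a$snapshots, `[[`, "values"),
                   lapply(b$snapshots, `[[`, "values"))

  a <- simulate_facilitation_ca(24, driver_values = c(0.8, 0.6),
                                steps_first = 30, steps_next = 10, seed = 5)
  b <- simulate_facilitation_ca(24, driver_values = c(0.8, 0.6),
                                steps_first = 30, steps_next = 10, seed = 5)
  expect_identical(lapply(a$snapshots, `[[`, "values"),
                   lapply(b$snapshots, `[[`, "values"))

  a <- simulate_turing_pde(30, driver_values = c(1.2, 1.0), relax_first = 30,
                           relax_next = 10, seed = 5)
  b <- simulate_turing_pde(30, driver_values = c(1.2, 1.0), relax_first = 30,
                           relax_next = 10, seed = 5)
  expect_identical(lapply(a$snapshots, `[[`, "values"),
                   lapply(b$snapshots, `[[`, "values"))
})

test_that("rainfall extremes set the local-feedback lattice's vegetated state", {
  s <- simulate_local_feedback(40, driver_values = c(3.5, 0.5),
                               relax_first = 80, relax_next = 80, seed = 6)
  high <- s$snapshots[[1]]; low <- s$snapshots[[2]]
  expect_gt(mean(high$values), 5)
  # near-homogeneous: small coefficient of variation
  expect_lt(sd(high$values) / mean(high$values), 0.15)
  expect_lt(mean(low$values), 0.5)
})

test_that("the facilitation CA conserves cell states and collapses when harsh", {
  s <- simulate_facilitation_ca(50, driver_values = c(0.9, 0.5, 0.05),
                                steps_first = 150, steps_next = 150, seed = 7)
  states <- attr(s, "state_grids")
  for (st in states) {
    expect_equal(sum(st == 1L) + sum(st == 0L) + sum(st == -1L), 50L * 50L)
  }
  expect_equal(mean(s$snapshots[[3]]$values), 0)
  # benign end: clusters (Moran's I above the reshuffle null band)
  set.seed(30)
  cb <- confidence_band(s$snapshots[[1]], "morans_i", n = 100)
  expect_gt(cb$observed, cb$upper)
})

test_that("without local interactions the CA arrangement is spatially random", {
  # facilitation off and dispersal fully global: no local mechanism remains
  s <- simulate_facilitation_ca(50, driver_values = c(0.9, 0.85),
                                params = list(f = 0, r = 0.15, delta = 1),
                                steps_first = 200, steps_next = 50, seed = 8)
  set.seed(31)
  cb <- confidence_band(s$snapshots[[2]], "morans_i", n = 200)
  expect_false(cb$significant)
})

test_that("CA transition probabilities are vetted", {
  expect_error(simulate_facilitation_ca(20, params = list(m = 1.4)),
               class = "spatialews_error_validation")
  expect_error(simulate_facilitation_ca(20, params = list(r = 0.5, f = 0.9)),
               class = "spatialews_error_validation")
  expect_error(simulate_facilitation_ca(20, driver_values = c(1.5, 0.5)),
               class = "spatialews_error_validation")
})

test_that("asynchronous CA updating runs and collapses the same way", {
  s <- simulate_facilitation_ca(30, driver_values = c(0.9, 0.05),
                                steps_first = 80, steps_next = 120,
                                async = TRUE, seed = 9)
  expect_lt(mean(s$snapshots[[2]]$values), 0.05)
})

test_that("the Turing model forms a periodic pattern with non-negative fields", {
  s <- simulate_turing_pde(60, driver_values = c(1.05, 1.0),
                           relax_first = 400, relax_next = 50, seed = 10)
  g <- s$snapshots[[2]]
  expect_true(all(g$values >= 0))
  ps <- periodogram2d(g)
  cls <- classify_spectrum(r_spectrum(ps), theta_spectrum(ps),
                           spectrum_null_bands(g))
  expect_true(cls$periodic)
  expect_gte(cls$dominant_wavenumber, 3L)
})

test_that("the explicit scheme refuses a CFL-violating time step", {
  expect_error(simulate_turing_pde(30, dt = 0.5, dx = 2),
               class = "spatialews_error_configuration")
})

test_that("Turing dominant wavelength is grid-size independent", {
  wl <- sapply(c(60, 100), function(n) {
    s <- simulate_turing_pde(n, driver_values = c(1.05, 1.0),
                             relax_first = 400, relax_next = 50, seed = 12)
    g <- s$snapshots[[2]]
    ps <- periodogram2d(g)
    cls <- classify_spectrum(r_spectrum(ps), theta_spectrum(ps),
                             spectrum_null_bands(g))
    cls$dominant_wavelength  # in cells; same dx so comparable
  })
  expect_lt(abs(wl[1] - wl[2]) / wl[2], 0.25)
})

test_that("each simulator shows an abrupt collapse on a long gradient", {
  s1 <- simulate_local_feedback(40, driver_values = c(3, 2.4, 2, 1.8, 1.55, 1.3),
                                relax_first = 80, relax_next = 60, seed = 13)
  m1 <- sapply(s1$snapshots, function(g) mean(g$values))
  expect_gt(max(m1[-length(m1)] / pmax(m1[-1], 1e-9)), 10)

  s2 <- simulate_facilitation_ca(50, driver_values = c(0.9, 0.6, 0.4, 0.3, 0.2, 0.1),
                                 steps_first = 200, steps_next = 150, seed = 13)
  m2 <- sapply(s2$snapshots, function(g) mean(g$values))
  expect_gt(max((m2[-length(m2)] + 1e-9) / (m2[-1] + 1e-9)), 10)

  s3 <- simulate_turing_pde(50, driver_values = c(1.1, 0.9, 0.75, 0.6, 0.45, 0.3),
                            relax_first = 400, relax_next = 150, seed = 13)
  m3 <- sapply(s3$snapshots, function(g) mean(g$values))
  expect_gt(max(m3[-length(m3)] / pmax(m3[-1], 1e-9)), 10)
})
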