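test_that("patch labelling matches hand-built configurations", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 1] <- 1; m[2, 2] <- 1   # L-triomino
  m[4, 4] <- 1; m[5, 4] <- 1                 # domino
  g <- spatial_grid(m, value_kind = "discrete_occupancy", boundary = "open")
  ps <- label_patches(g)
  expect_setequal(ps$sizes, c(3L, 2L))
  expect_equal(sort(unique(as.vector(ps$label_grid))), 0:2)

  expect_equal(label_patches(spatial_grid(matrix(0, 4, 4),
                                          value_kind = "discrete_occupancy"))$n_patches, 0L)
  all1 <- label_patches(spatial_grid(matrix(1, 6, 6),
                                     value_kind = "discrete_occupancy"))
  expect_equal(all1$sizes, 36L)

  # periodic wrap merges opposite-edge patches
  m2 <- matrix(0, 4, 4); m2[1, 2] <- 1; m2[4, 2] <- 1
  gp <- spatial_grid(m2, value_kind = "discrete_occupancy",
                     boundary = "periodic")
  expect_equal(label_patches(gp)$sizes, 2L)
  expect_equal(label_patches(gp, boundary = "open")$n_patches, 2L)

  # diagonal touching: separate under 4-connectivity, joined under 8
  m3 <- matrix(0, 4, 4); m3[1, 1] <- 1; m3[2, 2] <- 1
  g3 <- spatial_grid(m3, value_kind = "discrete_occupancy")
  expect_equal(label_patches(g3, connectivity = 4)$n_patches, 2L)
  expect_equal(label_patches(g3, connectivity = 8)$n_patches, 1L)
})

test_that("patch labelling agrees with the flood-fill oracle on random grids", {
  set.seed(18)
  for (rep in 1:25) {
    p <- runif(1, 0.25, 0.65)
    g <- random_occupancy(15, 15, p)
    for (conn in c(4L, 8L)) for (b in c("open", "periodic")) {
      got <- sort(label_patches(g, connectivity = conn, boundary = b)$sizes)
      want <- sort(flood_fill_sizes(g$values == 1, conn, b))
      expect_identical(got, as.integer(want))
    }
  }
})

test_that("patch sizes conserve foreground cells and nest across connectivity", {
  set.seed(19)
  for (rep in 1:10) {
    g <- random_occupancy(20, 20, runif(1, 0.2, 0.7))
    p4 <- label_patches(g, connectivity = 4)
    p8 <- label_patches(g, connectivity = 8)
    expect_equal(sum(p4$sizes), sum(g$values))
    expect_equal(sum(p8$sizes), sum(g$values))
    expect_gte(p4$n_patches, p8$n_patches)
  }
})

test_that("continuous grids binarize with a threshold", {
  g <- spatial_grid(matrix(c(0.1, 0.9, 0.8, 0.2), 2, 2))
  expect_equal(label_patches(g, threshold = 0.5)$n_patches, 2L)
  expect_error(label_patches(g), class = "spatialews_error_validation")
})

test_that("inverse cumulative counts are evaluated at distinct sizes", {
  ic <- inverse_cumulative(c(1, 1, 2, 5))
  expect_equal(ic$size, c(1L, 2L, 5L))
  expect_equal(ic$n_ge, c(4L, 2L, 1L))
  expect_equal(inverse_cumulative(7L)$n_ge, 1L)
  set.seed(20)
  sizes <- sample(1:50, 200, replace = TRUE)
  ic2 <- inverse_cumulative(sizes)
  expect_true(all(diff(ic2$n_ge) <= 0))
  expect_equal(ic2$n_ge[[1]], 200L)
  expect_warning(empty <- inverse_cumulative(integer(0)), "No patches")
  expect_equal(nrow(empty), 0L)
})

test_that("discrete MLE recovers a known power-law exponent and ranks families", {
  set.seed(22)
  x <- rpowerlaw(2000, exponent = 2.0, xmin = 1)
  ft <- fit_patch_distribution(x, families = c("power_law", "exponential"))
  pl <- ft[ft$family == "power_law", ]
  expect_lt(abs(pl$exponent - 2.0), 0.1)
  expect_equal(ft$family[[1]], "power_law")

  # geometric sample: exponential family must beat the pure power law
  y <- stats::rgeom(2000, 0.2) + 1L
  ft2 <- fit_patch_distribution(y, families = c("power_law", "exponential"))
  expect_equal(ft2$family[[1]], "exponential")

  expect_error(fit_patch_distribution(c(2, 2, 3)),
               class = "spatialews_error_insufficient_data")
  expect_error(fit_patch_distribution(rep(4L, 25)),
               class = "spatialews_error_degenerate")
})

test_that("truncated power law detects a cutoff in geometric-damped samples", {
  set.seed(23)
  # power law with a hard exponential damp
  x <- rpowerlaw(4000, exponent = 1.6, xmin = 1)
  keep <- stats::runif(4000) < exp(-x / 30)
  x <- x[keep]
  ft <- fit_patch_distribution(x, families = c("power_law", "power_law_cutoff"))
  expect_equal(ft$family[[1]], "power_law_cutoff")
  expect_gt(ft$rate[ft$family == "power_law_cutoff"], 0.005)
})

test_that("xmin can be chosen by the KS scan", {
  set.seed(24)
  x <- c(sample(1:3, 300, replace = TRUE), rpowerlaw(700, 1.8, xmin = 4))
  ft <- fit_patch_distribution(x, families = "power_law", xmin = "auto")
  expect_gte(ft$xmin[[1]], 2L)
  expect_equal(ft$n_tail[[1]], sum(x >= ft$xmin[[1]]))
})

test_that("morphology classification tracks histogram shape and inverts with values", {
  set.seed(25)
  # sparse high discs on low background -> spots
  base <- matrix(rnorm(64 * 64, 1, 0.1), 64, 64)
  for (c0 in list(c(16, 16), c(40, 44), c(56, 20))) {
    d <- outer(1:64, 1:64, function(i, j) (i - c0[1])^2 + (j - c0[2])^2)
    base[d < 16] <- 5
  }
  g <- spatial_grid(base)
  mo <- classify_periodic_morphology(g)
  expect_equal(mo$class, "spots")
  # inversion flips the skewness sign exactly and the call to gaps
  gi <- spatial_grid(max(base) - base)
  mi <- classify_periodic_morphology(gi)
  expect_equal(mi$histogram_skewness, -mo$histogram_skewness, tolerance = 1e-12)
  expect_equal(mi$class, "gaps")

  # white noise is homogeneous in nearly all replicates
  calls <- replicate(40, classify_periodic_morphology(
    spatial_grid(matrix(rnorm(32 * 32), 32, 32)))$class)
  expect_gte(mean(calls == "homogeneous"), 0.95)

  # balanced two-phase field: labyrinth (bimodal, near-zero skew)
  two <- matrix(c(rnorm(512, 0, 0.15), rnorm(512, 2, 0.15)), 32, 32)
  expect_equal(classify_periodic_morphology(spatial_grid(two))$class,
               "labyrinth")
  expect_equal(classify_periodic_morphology(spatial_grid(matrix(3, 4, 4)))$class,
               "homogeneous")
})
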