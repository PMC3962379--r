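#' Reshuffle surrogate: random permutation of cell values
#'
#' Removes all spatial structure while conserving the exact multiset of
#' values — hence spatial variance and skewness are conserved to the bit,
#' which is why this null is informative for spatial correlation, spectra
#' and patch structure but *not* for variance/skewness (see
#' [coarse_grain_null_test()] for those).
#'
#' @param grid A `spatial_grid`.
#' @return A `spatial_grid` with permuted values.
#' @export
reshuffle_surrogate <- function(grid) {
  validate_grid(grid)
  out <- grid
  out$values <- matrix(sample(as.vector(grid$values)),
                       nrow(grid$values), ncol(grid$values))
  out$label <- paste0(grid$label, " [reshuffled]")
  out
}

#' Gaussian surrogate: iid normal field with matched mean and variance
#'
#' Each cell is an independent draw from a normal law whose mean and
#' (population) variance equal those of the original grid. A valid null for
#' spatial skewness, correlation and spectra of continuous data; *invalid*
#' as a variance null, because the variance is matched by construction, and
#' inapplicable to discrete occupancy data.
#'
#' @param grid A continuous-valued `spatial_grid` with positive variance.
#' @return A continuous `spatial_grid` of iid normal draws.
#' @export
gaussian_surrogate <- function(grid) {
  validate_grid(grid)
  if (grid$value_kind == "discrete_occupancy") {
    abort_spatialews(
      "Gaussian surrogates apply to continuous data only; coarse-grain occupancy data first.",
      "inapplicable_null")
  }
  v <- grid$values
  sigma2 <- mean((v - mean(v))^2)
  if (sigma2 == 0) {
    abort_spatialews("Gaussian surrogate undefined for a constant grid.",
                     "undefined")
  }
  out <- grid
  out$values <- matrix(stats::rnorm(length(v), mean(v), sqrt(sigma2)),
                       nrow(v), ncol(v))
  out$value_kind <- "continuous"
  out$label <- paste0(grid$label, " [gaussian null]")
  out
}

# internal: resolve an indicator given by name into a function grid -> numeric
# vector; the name is also used to vet null-model validity.
resolve_statistic <- function(statistic, ...) {
  if (is.function(statistic)) {
    return(list(fn = statistic, name = "custom"))
  }
  name <- match.arg(statistic,
                    c("mean", "variance", "skewness", "morans_i",
                      "reddening"))
  fn <- switch(name,
    mean = function(g) c(mean = mean(g$values)),
    variance = function(g) c(variance = spatial_moments(g)$variance),
    skewness = function(g) {
      m <- spatial_moments(g)
      if (!m$skewness_defined) {
        abort_spatialews("Skewness undefined (zero variance).", "undefined")
      }
      c(skewness = m$skewness)
    },
    morans_i = function(g) c(morans_i = morans_i(g, ...)$morans_i),
    reddening = function(g) {
      c(reddening = reddening_index(periodogram2d(g), ...))
    })
  list(fn = fn, name = name)
}

#' Monte-Carlo confidence band for an indicator under a surrogate null
#'
#' Evaluates an indicator on `n` surrogate grids (default 200, level 0.95 —
#' the convention used for all bands in this package) and returns the
#' empirical quantile band together with the observed value and a
#' significance flag (observed outside the band). Works for scalar
#' indicators and for vector-valued statistics (per-bin bands).
#'
#' Validity guard: the reshuffle null conserves variance and skewness
#' exactly (the band degenerates onto the observed value), and the Gaussian
#' null fixes the variance by construction; requesting `variance` under
#' `method = "gaussian"` is refused unless `allow_invalid_null = TRUE`.
#'
#' @param grid A `spatial_grid`.
#' @param statistic Indicator name (`"mean"`, `"variance"`, `"skewness"`,
#'   `"morans_i"`, `"reddening"`) or a function `grid -> numeric`.
#' @param method `"reshuffle"` or `"gaussian"`.
#' @param n Number of surrogates (default 200).
#' @param level Band level (default 0.95).
#' @param allow_invalid_null Override the variance/Gaussian guard.
#' @param ... Passed to the named indicator (e.g. `lag`, `weights`).
#' @return A tibble with one row per statistic component: `statistic`,
#'   `observed`, `lower`, `upper`, `significant`, `method`, `n_surrogates`,
#'   `level`.
#' @export
confidence_band <- function(grid, statistic, method = c("reshuffle", "gaussian"),
                            n = 200L, level = 0.95,
                            allow_invalid_null = FALSE, ...) {
  method <- match.arg(method)
  res <- resolve_statistic(statistic, ...)
  if (res$name == "variance" && method == "gaussian" && !allow_invalid_null) {
    abort_spatialews(
      "The Gaussian surrogate fixes variance by construction and is not a valid variance null.",
      "invalid_null")
  }
  if (res$name %in% c("variance", "skewness") && method == "reshuffle") {
    rlang::warn(paste0(
      "Reshuffling conserves spatial ", res$name,
      " exactly; the band is degenerate. Use coarse_grain_null_test() instead."))
  }
  surrogate <- switch(method, reshuffle = reshuffle_surrogate,
                      gaussian = gaussian_surrogate)
  obs <- res$fn(grid)
  sims <- matrix(NA_real_, n, length(obs))
  for (b in seq_len(n)) sims[b, ] <- res$fn(surrogate(grid))
  band_tibble(obs, sims, res$name, method, level)
}

# internal: shared quantile-band assembly
band_tibble <- function(obs, sims, name, method, level) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q <- apply(sims, 2L, stats::quantile, probs = probs, names = FALSE)
  nm <- names(obs)
  if (is.null(nm)) nm <- paste0(name, seq_along(obs))
  tibble::tibble(statistic = nm, observed = as.numeric(obs),
                 lower = q[1L, ], upper = q[2L, ],
                 significant = as.numeric(obs) < q[1L, ] |
                               as.numeric(obs) > q[2L, ],
                 method = method, n_surrogates = nrow(sims), level = level)
}

#' Coarse-graining null test for spatial variance and skewness
#'
#' Reshuffling cannot test variance or skewness (it conserves them), so this
#' null compares the statistic of the coarse-grained observed grid against
#' the distribution of the same statistic over coarse-grained *reshuffles*:
#' averaging sub-blocks of a random matrix shrinks variability sharply,
#' while genuine spatial structure survives coarse-graining, so a structured
#' grid lands above the band.
#'
#' @param grid A `spatial_grid`.
#' @param sub Block size (>= 2 for a discriminating test; `sub = 1` is
#'   allowed but warned, since the coarse-grained matrix is then identical
#'   to the original and reshuffling conserves the moments).
#' @param statistic `"variance"` or `"skewness"`.
#' @param n,level As in [confidence_band()].
#' @param mode Coarse-graining mode, `"mean"` or (occupancy grids)
#'   `"count"`.
#' @return A tibble as in [confidence_band()], where `observed` is the
#'   statistic of the coarse-grained grid.
#' @export
coarse_grain_null_test <- function(grid, sub, statistic = c("variance", "skewness"),
                                   n = 200L, level = 0.95,
                                   mode = c("mean", "count")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (sub == 1L) {
    rlang::warn("sub = 1: the coarse-grained matrix is identical to the original; the test cannot discriminate.")
  }
  stat_fn <- function(g) {
    m <- spatial_moments(g)
    val <- if (statistic == "variance") m$variance else m$skewness
    stats::setNames(val, statistic)
  }
  obs <- stat_fn(coarse_grain(grid, sub, mode))
  sims <- matrix(NA_real_, n, 1L)
  for (b in seq_len(n)) {
    sims[b, 1L] <- stat_fn(coarse_grain(reshuffle_surrogate(grid), sub, mode))
  }
  out <- band_tibble(obs, sims, statistic, "coarse_grain_reshuffle", level)
  out$sub <- as.integer(sub)
  out
}

#' Analytic chi-squared band for binned periodogram power
#'
#' For a grid with no spatial structure the scaled periodogram ordinates
#' behave like scaled chi-squared variates: a conjugate pair of ordinates
#' contributes weight 2 and 2 degrees of freedom, a self-conjugate (real)
#' ordinate weight 1 and 1 df, so the summed power of a bin holding `m`
#' ordinates is distributed as `sigma_scaled * chisq(m)` with `m` the
#' ordinate count. On the scaled-power convention (total power 1 over
#' `N - 1` ordinates) the bin sum is approximately `chisq(m) / (N - 1)`.
#'
#' @param bin_counts Integer vector, ordinates per bin (>= 1).
#' @param level Two-sided level (default 0.95).
#' @param n_cells Total cell count `N` of the source grid. If supplied,
#'   `lower`/`upper` are on the scaled bin-sum scale; otherwise they are
#'   multipliers of the bin's expected power (`chisq(m)/m` quantiles).
#' @return Tibble with `count`, `lower`, `upper` (and `mean_power` when
#'   `n_cells` is given).
#' @export
chi2_spectrum_band <- function(bin_counts, level = 0.95, n_cells = NULL) {
  m <- as.integer(bin_counts)
  if (any(is.na(m) | m < 0L)) {
    abort_spatialews("Bin counts must be non-negative integers.",
                     "validation")
  }
  a <- (1 - level) / 2
  lo <- ifelse(m > 0L, stats::qchisq(a, df = m), 0)
  hi <- ifelse(m > 0L, stats::qchisq(1 - a, df = m), 0)
  if (is.null(n_cells)) {
    tibble::tibble(count = m,
                   lower = ifelse(m > 0L, lo / m, 0),
                   upper = ifelse(m > 0L, hi / m, 0))
  } else {
    scale <- 1 / (n_cells - 1)
    tibble::tibble(count = m, mean_power = m * scale,
                   lower = lo * scale, upper = hi * scale)
  }
}
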