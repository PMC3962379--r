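#' 2D periodogram of a snapshot
#'
#' Subtracts the spatial mean, takes the 2D discrete Fourier transform and
#' forms the periodogram (squared magnitude, divided by the cell count `N` so
#' that the unscaled ordinates satisfy Parseval's identity: their total
#' equals `N * variance`). With `scale_by_variance = TRUE` (the default and
#' the convention used throughout the package) ordinates are further divided
#' by `N * variance`, so the scaled total power is exactly 1 and spectra are
#' comparable across snapshots.
#'
#' The spectrum of a real grid is point-symmetric, so the full set of
#' ordinates over signed wavenumbers `kx in (-nx/2, nx/2]`,
#' `ky in (-ny/2, ny/2]` (DC excluded) is retained for radial/angular
#' binning, and a folded quadrant matrix over `0..floor(n/2)` per axis is
#' provided for display.
#'
#' @param grid A `spatial_grid`.
#' @param scale_by_variance Divide by `N * variance` (total scaled power 1).
#' @return A `power_spectrum` object: `ordinates` (tibble `kx`, `ky`,
#'   `power`, `ring`, `angle`), `folded` (matrix), `scaled`, `dc_removed`,
#'   `source_dims`, `total_power`.
#' @export
periodogram2d <- function(grid, scale_by_variance = TRUE) {
  validate_grid(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  n <- nr * nc
  sigma2 <- mean((v - mean(v))^2)
  if (scale_by_variance && sigma2 == 0) {
    abort_spatialews("Scaled spectrum undefined on a constant grid.",
                     "undefined")
  }
  x <- v - mean(v)
  p <- Mod(stats::fft(x))^2 / n          # unscaled: sum = N * sigma2
  if (scale_by_variance) p <- p / (n * sigma2)
  kx_idx <- rep(seq_len(nr) - 1L, times = nc)
  ky_idx <- rep(seq_len(nc) - 1L, each = nr)
  kx <- ifelse(kx_idx > nr %/% 2, kx_idx - nr, kx_idx)
  ky <- ifelse(ky_idx > nc %/% 2, ky_idx - nc, ky_idx)
  pw <- as.vector(p)
  keep <- !(kx == 0L & ky == 0L)         # remove DC (zero anyway)
  kx <- kx[keep]; ky <- ky[keep]; pw <- pw[keep]
  # ring index on normalised wavenumbers; equals round(sqrt(kx^2+ky^2)) for
  # square grids
  nmin <- min(nr, nc)
  ring <- floor(sqrt((kx / nr)^2 + (ky / nc)^2) * nmin + 0.5)
  ang <- (atan2(ky, kx) * 180 / pi) %% 180
  ord <- tibble::tibble(kx = kx, ky = ky, power = pw, ring = as.integer(ring),
                        angle = ang)
  folded <- compute_folded(ord, nr, nc)
  structure(list(ordinates = ord, folded = folded,
                 scaled = scale_by_variance, dc_removed = TRUE,
                 source_dims = c(nr, nc), total_power = sum(pw),
                 variance = sigma2),
            class = "power_spectrum")
}

# internal: fold symmetric ordinates onto the non-negative quadrant
compute_folded <- function(ord, nr, nc) {
  fk <- abs(ord$kx); fl <- abs(ord$ky)
  m <- matrix(0, nr %/% 2 + 1L, nc %/% 2 + 1L)
  lin <- fk + 1L + fl * nrow(m)
  sums <- rowsum(ord$power, lin)
  m[as.integer(rownames(sums))] <- sums[, 1L]
  dimnames(m) <- list(kx = 0:(nr %/% 2), ky = 0:(nc %/% 2))
  m
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d x %d source, %s, total power %.6g\n",
              x$source_dims[1L], x$source_dims[2L],
              if (x$scaled) "scaled by N*variance" else "unscaled",
              x$total_power))
  invisible(x)
}

#' Radial (r-) spectrum
#'
#' Sums the periodogram along concentric rings of constant distance from the
#' spectral origin. A peak at an interior ring diagnoses a periodic pattern;
#' the ring index is the number of pattern repetitions across the grid, so
#' the dominant wavelength is `grid extent / ring`.
#'
#' @param ps A `power_spectrum`.
#' @return A `radial_spectrum`: tibble with `wavenumber` (ring 1..floor(n/2)),
#'   `power`, `count`; attribute `discarded_power` holds the total power in
#'   rings beyond floor(n/2) (spectrum corners).
#' @export
r_spectrum <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  kmax <- min(ps$source_dims) %/% 2L
  agg <- dplyr::summarise(dplyr::group_by(ps$ordinates, .data$ring),
                          power = sum(.data$power),
                          count = dplyr::n(), .groups = "drop")
  kept <- dplyr::filter(agg, .data$ring >= 1L, .data$ring <= kmax)
  out <- tidyr::complete(kept, ring = seq_len(kmax),
                         fill = list(power = 0, count = 0L))
  out <- dplyr::arrange(dplyr::rename(out, wavenumber = "ring"),
                        .data$wavenumber)
  attr(out, "discarded_power") <- sum(agg$power[agg$ring > kmax])
  attr(out, "scaled") <- ps$scaled
  attr(out, "source_dims") <- ps$source_dims
  class(out) <- c("radial_spectrum", class(out))
  out
}

#' Angular (theta-) spectrum
#'
#' Sums the periodogram over equal angular sectors of `[0, 180)` degrees
#' (point symmetry of real-input spectra collapses the other half-plane).
#' Uniform sector power diagnoses an isotropic pattern; concentration in one
#' sector a preferred orientation (e.g. banded vegetation).
#'
#' @param ps A `power_spectrum`.
#' @param n_sectors Number of equal sectors (>= 4; default 12).
#' @return An `angular_spectrum`: tibble with `sector`, `angle_lo`,
#'   `angle_hi` (degrees), `power`, `count`.
#' @export
theta_spectrum <- function(ps, n_sectors = 12L) {
  stopifnot(inherits(ps, "power_spectrum"))
  n_sectors <- as.integer(n_sectors)
  if (n_sectors < 4L) {
    abort_spatialews("Need at least 4 angular sectors.", "validation")
  }
  width <- 180 / n_sectors
  sec <- pmin(floor(ps$ordinates$angle / width), n_sectors - 1L)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(sector = sec + 1L,
                                   power = ps$ordinates$power), .data$sector),
    power = sum(.data$power), count = dplyr::n(), .groups = "drop")
  out <- tidyr::complete(agg, sector = seq_len(n_sectors),
                         fill = list(power = 0, count = 0L))
  out <- dplyr::mutate(out, angle_lo = (.data$sector - 1L) * width,
                       angle_hi = .data$sector * width,
                       .after = "sector")
  attr(out, "scaled") <- ps$scaled
  attr(out, "source_dims") <- ps$source_dims
  class(out) <- c("angular_spectrum", class(out))
  out
}

#' Spectral reddening index
#'
#' The fraction of total spectral power carried by low wavenumbers (rings at
#' or below `low_fraction * floor(n/2)`). Under critical slowing down,
#' spatial variation concentrates at long wavelengths, so this index is
#' expected to rise along a degradation gradient ("reddening" of the
#' spectrum).
#'
#' @param ps A `power_spectrum` (scaled recommended; the index is a power
#'   fraction either way).
#' @param low_fraction Fraction of the wavenumber range counted as "low"
#'   (default 0.2).
#' @return A single number in `[0, 1]`.
#' @export
reddening_index <- function(ps, low_fraction = 0.2) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (low_fraction <= 0 || low_fraction >= 1) {
    abort_spatialews("`low_fraction` must be in (0, 1).", "validation")
  }
  cutoff <- low_fraction * (min(ps$source_dims) %/% 2L)
  tot <- sum(ps$ordinates$power)
  if (tot == 0) return(0)
  sum(ps$ordinates$power[ps$ordinates$ring <= cutoff]) / tot
}

#' Classify a snapshot's spectrum as periodic/aperiodic, isotropic/anisotropic
#'
#' Peak detection works on the mean power per ordinate in each ring
#' (`power / count`): ring sums grow with the ring's ordinate count even for
#' structureless data, whereas the mean ring power is flat for white noise,
#' decreasing for reddened (clustered) patterns, and peaked at an interior
#' ring only for genuinely periodic patterns. A pattern is called periodic
#' when the ring with the largest mean power (an interior local maximum by
#' construction) sits at wavenumber >= 3 (at least three pattern
#' repetitions across the extent), exceeds the null band upper limit, and
#' is prominent: at least twice the mean ordinate power of every ring in
#' the long-wavelength baseline (wavenumbers up to half the peak), which
#' separates a discrete spectral peak from the broad low-wavenumber excess
#' of reddened but aperiodic data. The
#' dominant wavelength is `grid extent / wavenumber` (in cells).
#'
#' Isotropy: a pattern is anisotropic when some sector of the theta-spectrum
#' exceeds its null band *and* carries more than `anisotropy_ratio` times
#' the mean sector power — the band alone (a white-noise null) flags any
#' patterned field, because realized patterns fluctuate between sectors far
#' more than white noise even when no orientation is preferred.
#'
#' Null bands come from [spectrum_null_bands()] (analytic chi-squared or
#' reshuffle ensemble) on the same binning; by default that helper widens
#' per-bin bands (Bonferroni across bins) so the family-wise false-positive
#' rate of this classification is controlled at the stated level.
#'
#' @param rs A `radial_spectrum`.
#' @param ts An `angular_spectrum`.
#' @param null_bands A list with elements `r` and `theta`, each a tibble with
#'   per-bin `lower`/`upper` columns on the same binning (see
#'   [spectrum_null_bands()]).
#' @param anisotropy_ratio Concentration threshold for the anisotropy call
#'   (default 2: some orientation carries at least twice the average power).
#' @return A one-row tibble: `periodic`, `dominant_wavenumber`,
#'   `dominant_wavelength`, `isotropic`, `dominant_angle` (sector midpoint in
#'   degrees, NA when isotropic).
#' @export
classify_spectrum <- function(rs, ts, null_bands, anisotropy_ratio = 2) {
  stopifnot(inherits(rs, "radial_spectrum"), inherits(ts, "angular_spectrum"))
  rb <- null_bands$r; tb <- null_bands$theta
  if (is.null(rb) || is.null(tb) ||
      nrow(rb) != nrow(rs) || nrow(tb) != nrow(ts)) {
    abort_spatialews("Null band binning does not match the spectra.",
                     "configuration")
  }
  mean_power <- ifelse(rs$count > 0, rs$power / rs$count, 0)
  k_star <- which.max(mean_power)
  baseline <- seq_len(max(1L, ceiling(k_star / 2)))
  prominent <- k_star > 1L &&
    mean_power[k_star] > 2 * max(mean_power[baseline])
  periodic <- rs$wavenumber[k_star] >= 3L &&
    rs$power[k_star] > rb$upper[k_star] && prominent
  dom_k <- if (periodic) rs$wavenumber[k_star] else NA_integer_
  extent <- min(attr(rs, "source_dims"))
  dom_wl <- if (periodic) extent / dom_k else NA_real_
  t_exceed <- ts$power > tb$upper &
    ts$power > anisotropy_ratio * mean(ts$power)
  isotropic <- !any(t_exceed)
  dom_angle <- if (isotropic) NA_real_ else {
    j <- which(t_exceed)[which.max(ts$power[which(t_exceed)])]
    (ts$angle_lo[j] + ts$angle_hi[j]) / 2
  }
  tibble::tibble(periodic = periodic,
                 dominant_wavenumber = as.integer(dom_k),
                 dominant_wavelength = dom_wl,
                 isotropic = isotropic,
                 dominant_angle = dom_angle)
}

#' Null bands for radial and angular spectra
#'
#' Builds per-bin confidence bands for the r- and theta-spectrum of a grid
#' under the no-spatial-structure null, either analytically (chi-squared law
#' for periodogram bin sums, see [chi2_spectrum_band()]) or by a reshuffle
#' surrogate ensemble. With `adjust = "bonferroni"` (default) the per-bin
#' level is tightened to `1 - (1 - level)/n_bins` so that the family-wise
#' error of peak detection across bins is held at `level`; use
#' `adjust = "none"` for pointwise bands (e.g. for plotting against figures).
#'
#' @param grid A `spatial_grid` (used for dimensions, variance and, for the
#'   reshuffle method, the surrogate values).
#' @param n_sectors Sectors for the theta-spectrum.
#' @param method `"chi2"` (analytic) or `"reshuffle"` (ensemble).
#' @param level Family-wise (or pointwise, per `adjust`) level, default 0.95.
#' @param n_surrogates Ensemble size for `method = "reshuffle"`.
#' @param adjust `"bonferroni"` or `"none"`.
#' @return List with tibbles `r` and `theta`, each with `lower`/`upper`
#'   per bin on the scaled-power scale.
#' @export
spectrum_null_bands <- function(grid, n_sectors = 12L,
                                method = c("chi2", "reshuffle"),
                                level = 0.95, n_surrogates = 200L,
                                adjust = c("bonferroni", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  ps <- periodogram2d(grid, scale_by_variance = TRUE)
  rs <- r_spectrum(ps)
  ts <- theta_spectrum(ps, n_sectors)
  lev_r <- if (adjust == "bonferroni") 1 - (1 - level) / nrow(rs) else level
  lev_t <- if (adjust == "bonferroni") 1 - (1 - level) / nrow(ts) else level
  n <- prod(ps$source_dims)
  if (method == "chi2") {
    r_band <- chi2_spectrum_band(rs$count, level = lev_r, n_cells = n)
    t_band <- chi2_spectrum_band(ts$count, level = lev_t, n_cells = n)
    list(r = dplyr::bind_cols(rs[, "wavenumber"], r_band[, c("lower", "upper")]),
         theta = dplyr::bind_cols(ts[, "sector"], t_band[, c("lower", "upper")]),
         method = method, level = level, adjust = adjust)
  } else {
    rs_mat <- matrix(0, n_surrogates, nrow(rs))
    ts_mat <- matrix(0, n_surrogates, nrow(ts))
    for (b in seq_len(n_surrogates)) {
      sg <- reshuffle_surrogate(grid)
      psb <- periodogram2d(sg, scale_by_variance = TRUE)
      rs_mat[b, ] <- r_spectrum(psb)$power
      ts_mat[b, ] <- theta_spectrum(psb, n_sectors)$power
    }
    qr <- apply(rs_mat, 2L, stats::quantile,
                probs = c((1 - lev_r) / 2, 1 - (1 - lev_r) / 2), names = FALSE)
    qt <- apply(ts_mat, 2L, stats::quantile,
                probs = c((1 - lev_t) / 2, 1 - (1 - lev_t) / 2), names = FALSE)
    list(r = tibble::tibble(wavenumber = rs$wavenumber,
                            lower = qr[1L, ], upper = qr[2L, ]),
         theta = tibble::tibble(sector = ts$sector,
                                lower = qt[1L, ], upper = qt[2L, ]),
         method = method, level = level, adjust = adjust)
  }
}
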