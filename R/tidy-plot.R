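#' @export
tidy.patch_size_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "patch_size_fit")
  out
}

#' @export
glance.patch_size_fit <- function(x, ...) {
  tibble::tibble(best_family = x$family[[1L]], n_tail = x$n_tail[[1L]],
                 xmin = x$xmin[[1L]], best_aic = x$aic[[1L]],
                 n_families = nrow(x))
}

#' @export
tidy.trend_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "trend_result")
  out
}

#' @export
glance.trend_result <- tidy.trend_result

#' @export
tidy.indicator_trajectory <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "indicator_trajectory")
  out
}

#' @export
glance.indicator_trajectory <- function(x, ...) {
  tibble::tibble(indicator = attr(x, "indicator") %||% "custom",
                 n = nrow(x), n_valid = sum(x$valid))
}

#' @export
tidy.patch_set <- function(x, ...) {
  tibble::tibble(patch = seq_along(x$sizes), size = x$sizes)
}

#' @export
glance.patch_set <- function(x, ...) {
  tibble::tibble(n_patches = x$n_patches, foreground_cells = sum(x$sizes),
                 largest = if (x$n_patches) max(x$sizes) else 0L,
                 connectivity = x$connectivity, boundary = x$boundary)
}

#' @export
tidy.ews_report <- function(x, ...) x$indicators

#' @export
glance.ews_report <- function(x, ...) {
  tibble::tibble(periodic = x$routing$periodic,
                 isotropic = x$routing$isotropic,
                 patchy = x$routing$patchy,
                 n_indicators = length(unique(x$indicators$indicator)),
                 seed = x$provenance$seed)
}

#' Plot a spatial grid as a raster
#'
#' @param object A `spatial_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spatial_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot a radial or angular spectrum
#'
#' @param object A `radial_spectrum` or `angular_spectrum`.
#' @param bands Optional band tibble (columns `lower`, `upper`) from
#'   [spectrum_null_bands()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_spectrum <- function(object, bands = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$power))
  if (!is.null(bands)) {
    df$lower <- bands$lower; df$upper <- bands$upper
    p <- p + ggplot2::geom_ribbon(
      data = df, ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "wavenumber (ring)", y = "power") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.radial_spectrum
#' @export
autoplot.angular_spectrum <- function(object, bands = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$angle <- (df$angle_lo + df$angle_hi) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$power))
  if (!is.null(bands)) {
    df$lower <- bands$lower; df$upper <- bands$upper
    p <- p + ggplot2::geom_ribbon(
      data = df, ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "orientation (degrees)", y = "power") +
    ggplot2::theme_minimal()
}

#' Plot an indicator trajectory along the gradient
#'
#' @param object An `indicator_trajectory` (optionally carrying band
#'   columns `lower`/`upper` from [run_ews()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.indicator_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value))
  if (!is.null(df$lower) && any(is.finite(df$lower))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), fill = "grey80")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "rank along degradation gradient",
                  y = attr(object, "indicator") %||% "indicator") +
    ggplot2::theme_minimal()
}

#' Plot the inverse cumulative patch-size distribution
#'
#' @param sizes Patch sizes, a `patch_set`, or a tibble from
#'   [inverse_cumulative()].
#' @return A ggplot object on log-log axes.
#' @export
plot_inverse_cumulative <- function(sizes) {
  df <- if (is.data.frame(sizes)) sizes else inverse_cumulative(sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$n_ge)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "patch size s (cells)", y = "number of patches >= s") +
    ggplot2::theme_minimal()
}

#' Plot all indicator trajectories of a report
#'
#' @param object An `ews_report`.
#' @param ... Unused.
#' @return A ggplot object faceted by indicator.
#' @export
autoplot.ews_report <- function(object, ...) {
  df <- object$indicators
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value))
  if (!is.null(df$lower)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), fill = "grey80")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = "rank along degradation gradient", y = NULL) +
    ggplot2::theme_minimal()
}
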