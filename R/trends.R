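#' Evaluate an indicator along a gradient of snapshots
#'
#' Applies an indicator independently to each snapshot of a
#' [gradient_sequence()], keeping gradient order. Snapshots where the
#' indicator is undefined (e.g. skewness of a constant grid) are flagged,
#' not silently dropped.
#'
#' @param seq A `gradient_sequence`.
#' @param indicator Name (`"mean"`, `"variance"`, `"skewness"`,
#'   `"morans_i"`, `"reddening"`) or a function `spatial_grid -> scalar`.
#' @param ... Passed to the named indicator.
#' @return An `indicator_trajectory` tibble: `rank`, `stress`, `value`,
#'   `valid`; attributes `indicator` (name) and `n_valid`.
#' @export
indicator_trajectory <- function(seq, indicator, ...) {
  if (!inherits(seq, "gradient_sequence")) {
    abort_spatialews("`seq` must be a gradient_sequence.", "validation")
  }
  res <- resolve_statistic(indicator, ...)
  vals <- vapply(seq$snapshots, function(g) {
    tryCatch(as.numeric(res$fn(g))[[1L]],
             spatialews_error_undefined = function(e) NA_real_)
  }, numeric(1L))
  out <- tibble::tibble(rank = seq_along(vals), stress = seq$stress,
                        value = vals, valid = !is.na(vals))
  attr(out, "indicator") <- res$name
  attr(out, "n_valid") <- sum(!is.na(vals))
  class(out) <- c("indicator_trajectory", class(out))
  out
}

#' Trend statistic of an indicator along the gradient
#'
#' Kendall's tau-b (tie-corrected; the default) or Pearson's r between
#' stress (or rank) and the indicator values, on valid pairs only. P-values
#' come from [stats::cor.test()]: exact for small untied Kendall samples,
#' tie-corrected asymptotic otherwise.
#'
#' @param traj An `indicator_trajectory` (or any data frame with columns
#'   `stress`/`rank` and `value`).
#' @param method `"kendall"` or `"pearson"`.
#' @param use_stress Correlate against stress values (default) or ranks.
#'   Kendall's tau is identical for the two on monotone gradients.
#' @return A `trend_result` one-row tibble: `method`, `statistic`,
#'   `p_value`, `n`.
#' @export
trend_statistic <- function(traj, method = c("kendall", "pearson"),
                            use_stress = TRUE) {
  method <- match.arg(method)
  x <- if (use_stress && !is.null(traj$stress)) traj$stress else traj$rank
  y <- traj$value
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3L) {
    abort_spatialews("Need at least 3 valid points for a trend.",
                     "insufficient_data")
  }
  if (stats::sd(y) == 0) {
    out <- tibble::tibble(method = method, statistic = NA_real_,
                          p_value = NA_real_, n = length(y))
    attr(out, "undefined_trend") <- TRUE
    class(out) <- c("trend_result", class(out))
    return(out)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  out <- tibble::tibble(method = method,
                        statistic = unname(ct$estimate),
                        p_value = ct$p.value, n = length(y))
  class(out) <- c("trend_result", class(out))
  out
}
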