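#' Route a gradient data set to the appropriate indicator battery
#'
#' Implements the decision flow for spatial early-warning analysis. Discrete
#' occupancy data are first coarse-grained (default 5x5 occupied-cell
#' counts) into quantitative local-abundance grids. Each snapshot's
#' r-/theta-spectrum is then classified (periodic? isotropic?) against null
#' bands, and the data set routed by majority vote across snapshots;
#' per-snapshot calls are reported so conflicting classifications are
#' visible. Patchiness is decided by a two-phase criterion: occupancy data
#' are patchy by definition; continuous data are called patchy when the
#' pixel-value histogram is bimodal (bimodality coefficient > 5/9) in a
#' majority of snapshots.
#'
#' @param seq A `gradient_sequence`.
#' @param sub Coarse-graining block size for discrete data (default 5; the
#'   block size can affect indicator behaviour — see the report warning).
#' @param n_sectors Sectors for the theta-spectrum.
#' @param band_method `"chi2"` or `"reshuffle"` null bands for
#'   classification.
#' @param level Band level.
#' @return An `ews_routing` list: `periodic`, `isotropic`, `patchy`,
#'   `value_kind`, `coarse_grained`, `sub`, `per_snapshot` (tibble),
#'   `conflicted` (logical), `working_seq` (the analysis sequence, coarse-
#'   grained for discrete input).
#' @export
route <- function(seq, sub = 5L, n_sectors = 12L,
                  band_method = c("chi2", "reshuffle"), level = 0.95) {
  band_method <- match.arg(band_method)
  if (!inherits(seq, "gradient_sequence")) {
    abort_spatialews("`seq` must be a gradient_sequence.", "validation")
  }
  kind <- seq$snapshots[[1L]]$value_kind
  discrete <- kind == "discrete_occupancy"
  working <- if (discrete) {
    snaps <- lapply(seq$snapshots, coarse_grain, sub = sub, mode = "count")
    gradient_sequence(snaps, stress = seq$stress, direction = seq$direction)
  } else seq
  per <- purrr::map_dfr(seq_along(working$snapshots), function(i) {
    g <- working$snapshots[[i]]
    if (mean((g$values - mean(g$values))^2) == 0) {
      return(tibble::tibble(rank = i, periodic = NA, isotropic = NA,
                            dominant_wavenumber = NA_integer_,
                            dominant_wavelength = NA_real_, bimodal = NA))
    }
    ps <- periodogram2d(g)
    cls <- classify_spectrum(r_spectrum(ps), theta_spectrum(ps, n_sectors),
                             spectrum_null_bands(g, n_sectors,
                                                 method = band_method,
                                                 level = level))
    morph <- classify_periodic_morphology(g)
    tibble::tibble(rank = i, periodic = cls$periodic,
                   isotropic = cls$isotropic,
                   dominant_wavenumber = cls$dominant_wavenumber,
                   dominant_wavelength = cls$dominant_wavelength,
                   bimodal = morph$modality == 2L)
  })
  vote <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(FALSE)
    mean(x) > 0.5
  }
  periodic <- vote(per$periodic)
  isotropic <- vote(per$isotropic)
  patchy <- if (discrete) TRUE else vote(per$bimodal)
  conflicted <- !all(per$periodic[!is.na(per$periodic)] == periodic)
  structure(list(periodic = periodic, isotropic = isotropic, patchy = patchy,
                 value_kind = kind, coarse_grained = discrete,
                 sub = if (discrete) as.integer(sub) else NA_integer_,
                 per_snapshot = per, conflicted = conflicted,
                 working_seq = working),
            class = "ews_routing")
}

#' @export
print.ews_routing <- function(x, ...) {
  cat(sprintf("<ews_routing> periodic=%s isotropic=%s patchy=%s (%s%s)%s\n",
              x$periodic, x$isotropic, x$patchy, x$value_kind,
              if (x$coarse_grained) sprintf(", coarse-grained %dx%d", x$sub, x$sub) else "",
              if (x$conflicted) " [per-snapshot conflict, majority rule]" else ""))
  invisible(x)
}

# internal: trajectory + bands + trend for one indicator over the working seq
battery_indicator <- function(working, name, n_surrogates, level, ...) {
  traj <- indicator_trajectory(working, name, ...)
  bands <- purrr::map_dfr(seq_along(working$snapshots), function(i) {
    g <- working$snapshots[[i]]
    if (name %in% c("variance", "skewness")) {
      # reshuffling conserves these moments: no valid per-snapshot null
      return(tibble::tibble(rank = i, lower = NA_real_, upper = NA_real_,
                            significant = NA, null = "no valid null"))
    }
    bb <- tryCatch(
      suppressWarnings(confidence_band(g, name, method = "reshuffle",
                                       n = n_surrogates, level = level, ...)),
      error = function(e) NULL)
    if (is.null(bb)) {
      tibble::tibble(rank = i, lower = NA_real_, upper = NA_real_,
                     significant = NA, null = "no valid null")
    } else {
      tibble::tibble(rank = i, lower = bb$lower, upper = bb$upper,
                     significant = bb$significant, null = "reshuffle")
    }
  })
  list(trajectory = dplyr::left_join(traj, bands, by = "rank"),
       trend = tryCatch(trend_statistic(traj), error = function(e) NULL))
}

#' Run the full early-warning analysis on a gradient data set
#'
#' Routes the data set (see [route()]) and executes the indicated battery:
#' non-periodic data get the generic leading indicators (spatial variance,
#' skewness, lag-1 Moran's I) plus the spectral reddening index, each with
#' per-snapshot null bands where a valid null exists (reshuffling conserves
#' variance/skewness, so those carry a "no valid null" marker and are
#' covered instead by the coarse-graining null test on the most stressed
#' snapshot); patchy data additionally get patch labelling and patch-size
#' distribution fits per snapshot; periodic data get per-snapshot
#' morphology calls and the dominant-wavelength trajectory. Every
#' trajectory gets a Kendall trend statistic. Deterministic under a fixed
#' `seed`.
#'
#' @param seq A `gradient_sequence`.
#' @param seed Integer seed for all surrogate randomness.
#' @param sub Coarse-graining block for discrete data (default 5).
#' @param n_surrogates,level Null-band settings (defaults 200, 0.95).
#' @param band_method Spectral classification band method.
#' @param fit_families Families for patch-size fits.
#' @param patch_threshold Binarization threshold for continuous patchy
#'   data; default is the midpoint between the 10% and 90% value quantiles.
#' @return An `ews_report`: list with `routing`, `indicators` (tibble),
#'   `trends` (tibble), `morphology` (tibble or NULL), `patch_fits`
#'   (tibble or NULL), `coarse_null` (tibble or NULL), `provenance`.
#' @export
run_ews <- function(seq, seed = 1L, sub = 5L, n_surrogates = 200L,
                    level = 0.95, band_method = c("chi2", "reshuffle"),
                    fit_families = c("power_law", "power_law_cutoff",
                                     "exponential", "lognormal"),
                    patch_threshold = NULL) {
  band_method <- match.arg(band_method)
  set.seed(seed)
  routing <- route(seq, sub = sub, band_method = band_method, level = level)
  working <- routing$working_seq
  indicators <- NULL; trends <- list(); morphology <- NULL
  patch_fits <- NULL; coarse_null <- NULL
  gather <- function(name, res) {
    tr <- tibble::as_tibble(as.data.frame(res$trajectory))
    attr(tr, "indicator") <- NULL; attr(tr, "n_valid") <- NULL
    tr$indicator <- name
    indicators <<- dplyr::bind_rows(indicators, tr)
    if (!is.null(res$trend)) {
      t2 <- res$trend; t2$indicator <- name
      trends[[name]] <<- t2
    }
  }
  if (!routing$periodic) {
    gather("variance", battery_indicator(working, "variance", n_surrogates, level))
    gather("skewness", battery_indicator(working, "skewness", n_surrogates, level))
    gather("morans_i", battery_indicator(working, "morans_i", n_surrogates, level))
    gather("reddening", battery_indicator(working, "reddening", n_surrogates, level))
    # variance/skewness have no reshuffle null; run the coarse-graining test
    # on the most stressed snapshot of the *original* data
    last <- seq$snapshots[[length(seq$snapshots)]]
    cg_mode <- if (routing$value_kind == "discrete_occupancy") "count" else "mean"
    coarse_null <- tryCatch(
      dplyr::bind_rows(
        coarse_grain_null_test(last, sub = sub, statistic = "variance",
                               n = n_surrogates, level = level, mode = cg_mode),
        coarse_grain_null_test(last, sub = sub, statistic = "skewness",
                               n = n_surrogates, level = level, mode = cg_mode)),
      error = function(e) NULL)
  } else {
    morphology <- purrr::map_dfr(seq_along(working$snapshots), function(i) {
      m <- classify_periodic_morphology(working$snapshots[[i]])
      m$rank <- i
      m
    })
    wl <- routing$per_snapshot[, c("rank", "dominant_wavelength")]
    traj <- tibble::tibble(rank = wl$rank, stress = working$stress,
                           value = wl$dominant_wavelength,
                           valid = !is.na(wl$dominant_wavelength))
    attr(traj, "indicator") <- "dominant_wavelength"
    class(traj) <- c("indicator_trajectory", class(traj))
    tr <- tryCatch(trend_statistic(traj), error = function(e) NULL)
    traj <- tibble::as_tibble(as.data.frame(traj))
    attr(traj, "indicator") <- NULL; attr(traj, "n_valid") <- NULL
    traj$indicator <- "dominant_wavelength"
    indicators <- dplyr::bind_rows(indicators, traj)
    if (!is.null(tr)) { tr$indicator <- "dominant_wavelength"; trends[["dominant_wavelength"]] <- tr }
  }
  if (routing$patchy) {
    use_occ <- routing$value_kind == "discrete_occupancy"
    patch_fits <- purrr::map_dfr(seq_along(seq$snapshots), function(i) {
      g <- seq$snapshots[[i]]
      thr <- if (use_occ) NULL else patch_threshold %||%
        mean(stats::quantile(g$values, c(0.1, 0.9)))
      res <- tryCatch({
        ps <- label_patches(g, threshold = thr)
        ft <- fit_patch_distribution(ps$sizes, families = fit_families)
        ft$rank <- i
        ft$n_patches <- ps$n_patches
        ft
      }, error = function(e) {
        tibble::tibble(family = NA_character_, rank = i,
                       note = conditionMessage(e))
      })
      res
    })
  }
  structure(list(
    routing = routing[c("periodic", "isotropic", "patchy", "value_kind",
                        "coarse_grained", "sub", "conflicted")],
    per_snapshot = routing$per_snapshot,
    indicators = indicators,
    trends = if (length(trends)) dplyr::bind_rows(trends) else NULL,
    morphology = morphology,
    patch_fits = patch_fits,
    coarse_null = coarse_null,
    provenance = list(seed = as.integer(seed), sub = as.integer(sub),
                      n_surrogates = as.integer(n_surrogates), level = level,
                      band_method = band_method,
                      config_hash = rlang::hash(list(seed, sub, n_surrogates,
                                                     level, band_method,
                                                     fit_families)),
                      version = as.character(utils::packageVersion("spatialews")),
                      note = paste("Discrete data coarse-grained before analysis;",
                                   "the sub-matrix size may affect indicator behaviour."))),
    class = "ews_report")
}

#' @export
print.ews_report <- function(x, ...) {
  r <- x$routing
  cat(sprintf("<ews_report> periodic=%s isotropic=%s patchy=%s\n",
              r$periodic, r$isotropic, r$patchy))
  if (!is.null(x$trends)) {
    cat("Trends (Kendall):\n")
    for (i in seq_len(nrow(x$trends))) {
      cat(sprintf("  %-20s tau = %+.3f  (p = %.3g, n = %d)\n",
                  x$trends$indicator[[i]], x$trends$statistic[[i]],
                  x$trends$p_value[[i]], x$trends$n[[i]]))
    }
  }
  invisible(x)
}

#' Serialize an EWS report to JSON
#'
#' Writes the report's tables and routing to a JSON file that
#' [read_ews_report()] restores losslessly (tables as data frames).
#'
#' @param report An `ews_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ews_report <- function(report, path) {
  payload <- list(
    routing = report$routing,
    per_snapshot = report$per_snapshot,
    indicators = report$indicators,
    trends = report$trends,
    morphology = report$morphology,
    patch_fits = report$patch_fits,
    coarse_null = report$coarse_null,
    provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a serialized EWS report
#'
#' @param path JSON file written by [write_ews_report()].
#' @return An `ews_report` (tables as tibbles).
#' @export
read_ews_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_tbl <- function(x) if (is.null(x) || length(x) == 0L) NULL else tibble::as_tibble(x)
  structure(list(routing = p$routing,
                 per_snapshot = to_tbl(p$per_snapshot),
                 indicators = to_tbl(p$indicators),
                 trends = to_tbl(p$trends),
                 morphology = to_tbl(p$morphology),
                 patch_fits = to_tbl(p$patch_fits),
                 coarse_null = to_tbl(p$coarse_null),
                 provenance = p$provenance),
            class = "ews_report")
}
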