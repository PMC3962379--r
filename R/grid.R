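#' Construct a spatial grid snapshot
#'
#' A `spatial_grid` wraps one 2D raster snapshot of an ecological state
#' variable (e.g. vegetation biomass per cell, or presence/absence) together
#' with the metadata every indicator needs: whether values are continuous or
#' discrete, and which boundary convention (periodic or open) applies.
#' Row 1 of the matrix is the top row of the landscape; storage is row-major
#' in the sense that `values[i, j]` is the cell in row `i`, column `j`.
#'
#' @param values Numeric matrix (at least 2 x 2) of finite values.
#' @param value_kind One of `"continuous"`, `"discrete_occupancy"` (all values
#'   in \{0, 1\}) or `"discrete_multistate"`.
#' @param boundary `"open"` (field data) or `"periodic"` (simulated lattices).
#' @param label Free-text label carried through reports.
#'
#' @return An object of class `spatial_grid`.
#' @export
#' @examples
#' g <- spatial_grid(matrix(rnorm(100), 10, 10))
#' dim(g)
spatial_grid <- function(values,
                         value_kind = c("continuous", "discrete_occupancy",
                                        "discrete_multistate"),
                         boundary = c("open", "periodic"),
                         label = "") {
  value_kind <- match.arg(value_kind)
  boundary <- match.arg(boundary)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_spatialews("`values` must be a numeric matrix.", "validation")
  }
  storage.mode(values) <- "double"
  g <- structure(list(values = values, value_kind = value_kind,
                      boundary = boundary, label = label),
                 class = "spatial_grid")
  validate_grid(g)
}

#' Validate a spatial grid
#'
#' Checks the invariants: dimensions at least 2 x 2, all values finite, and
#' occupancy grids restricted to \{0, 1\}.
#'
#' @param grid A `spatial_grid`.
#' @return The validated grid, invisibly usable in pipes.
#' @export
validate_grid <- function(grid) {
  if (!inherits(grid, "spatial_grid")) {
    abort_spatialews("Not a spatial_grid object.", "validation")
  }
  v <- grid$values
  if (is.null(dim(v)) || nrow(v) < 2L || ncol(v) < 2L) {
    abort_spatialews("Grid must have at least 2 rows and 2 columns.",
                     "validation")
  }
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    abort_spatialews(
      sprintf("Non-finite value at row %d, column %d.", bad[1L], bad[2L]),
      "validation")
  }
  if (grid$value_kind == "discrete_occupancy" && !all(v %in% c(0, 1))) {
    bad <- which(matrix(!(v %in% c(0, 1)), nrow(v)), arr.ind = TRUE)[1L, ]
    abort_spatialews(
      sprintf("Occupancy grid holds value %g at row %d, column %d; only 0/1 allowed.",
              v[bad[1L], bad[2L]], bad[1L], bad[2L]),
      "validation")
  }
  grid
}

#' @export
dim.spatial_grid <- function(x) dim(x$values)

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> %d x %d, %s values, %s boundary%s\n",
              nrow(x$values), ncol(x$values), x$value_kind, x$boundary,
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' @export
as.matrix.spatial_grid <- function(x, ...) x$values

#' Tidy a grid into long (row, col, value) form
#'
#' @param x A `spatial_grid`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `value`.
#' @export
as_tibble.spatial_grid <- function(x, ...) {
  v <- x$values
  tibble::tibble(row = rep(seq_len(nrow(v)), times = ncol(v)),
                 col = rep(seq_len(ncol(v)), each = nrow(v)),
                 value = as.vector(v))
}

#' Read a raster snapshot from a delimited text file
#'
#' Row 1 of the file becomes row 1 (the top row) of the grid. The delimiter is
#' auto-detected among comma, tab and whitespace unless given explicitly.
#'
#' @param path Path to a plain-text matrix file.
#' @param delimiter Single character, or `NULL` to auto-detect.
#' @param value_kind,boundary,label Passed to [spatial_grid()].
#' @return A validated `spatial_grid`.
#' @export
read_grid <- function(path, delimiter = NULL,
                      value_kind = "continuous", boundary = "open",
                      label = basename(path)) {
  if (!file.exists(path)) {
    abort_spatialews(sprintf("File not found: %s", path), "io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort_spatialews(sprintf("File is empty: %s", path), "format")
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", lines[[1L]], fixed = TRUE)) ","
      else if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t"
      else " "
  }
  split_re <- if (delimiter %in% c(" ", "")) "[[:space:]]+" else
    paste0("[", delimiter, "]")
  cells <- lapply(lines, function(l) {
    parts <- strsplit(trimws(l), split_re)[[1L]]
    parts[nzchar(parts)]
  })
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[[1L]])[[1L]]
    abort_spatialews(
      sprintf("Ragged rows: row %d has %d cells but row 1 has %d.",
              bad, widths[[bad]], widths[[1L]]),
      "format")
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(cells),
           ncol = widths[[1L]], byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    abort_spatialews(
      sprintf("Non-numeric cell '%s' at row %d, column %d.",
              cells[[bad[1L]]][[bad[2L]]], bad[1L], bad[2L]),
      "parse")
  }
  spatial_grid(vals, value_kind = value_kind, boundary = boundary,
               label = label)
}

#' Write a raster snapshot to a delimited text file
#'
#' Values are written at 17 significant digits so that a read/write roundtrip
#' is lossless for double-precision data.
#'
#' @param grid A validated `spatial_grid`.
#' @param path Output file path.
#' @param delimiter Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, delimiter = ",") {
  validate_grid(grid)
  v <- grid$values
  txt <- apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                        collapse = delimiter))
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_spatialews(sprintf("Cannot write to %s", path), "io")
  invisible(path)
}

#' Coarse-grain a grid over non-overlapping square blocks
#'
#' Replaces each `sub` x `sub` block by its mean (`mode = "mean"`) or by the
#' number of occupied cells (`mode = "count"`, occupancy grids only). Trailing
#' rows/columns that do not fill a block are discarded, so blocks stay
#' non-overlapping and equal-sized. `sub = 1` returns a copy of the input.
#' Coarse-graining converts discrete occupancy into a quantitative local
#' abundance and is also the building block of the variance/skewness null
#' model (see [coarse_grain_null_test()]).
#'
#' @param grid A `spatial_grid`.
#' @param sub Block edge length (positive integer).
#' @param mode `"mean"` or `"count"`.
#' @return A `spatial_grid` of dimension `floor(nrow/sub) x floor(ncol/sub)`.
#' @export
#' @examples
#' occ <- spatial_grid(matrix(rbinom(100, 1, .4), 10, 10),
#'                     value_kind = "discrete_occupancy")
#' coarse_grain(occ, 5, "count")
coarse_grain <- function(grid, sub, mode = c("mean", "count")) {
  validate_grid(grid)
  mode <- match.arg(mode)
  sub <- as.integer(sub)
  if (length(sub) != 1L || is.na(sub) || sub < 1L) {
    abort_spatialews("`sub` must be a positive integer.", "validation")
  }
  if (mode == "count" && grid$value_kind != "discrete_occupancy") {
    abort_spatialews("mode = 'count' requires a discrete occupancy grid.",
                     "validation")
  }
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  nr2 <- nr %/% sub; nc2 <- nc %/% sub
  if (nr2 < 2L || nc2 < 2L) {
    abort_spatialews(
      sprintf("Coarse-graining %dx%d by sub = %d gives a %dx%d grid; need at least 2x2.",
              nr, nc, sub, nr2, nc2),
      "degenerate")
  }
  if (sub == 1L) {
    out <- grid
    out$label <- grid$label
    return(out)
  }
  m <- grid$values[seq_len(nr2 * sub), seq_len(nc2 * sub), drop = FALSE]
  a <- array(m, c(sub, nr2, sub, nc2))
  sums <- apply(a, c(2L, 4L), sum)
  out_vals <- if (mode == "mean") sums / sub^2 else round(sums)
  # block means/counts are quantitative local abundances whatever the input
  spatial_grid(out_vals, value_kind = "continuous", boundary = grid$boundary,
               label = grid$label)
}

#' Build an ordered gradient of snapshots
#'
#' The unit of trend analysis: an ordered set of snapshots along a stress
#' gradient (stress values or integer ranks, strictly monotone).
#'
#' @param snapshots List of `spatial_grid` objects sharing dimensions and
#'   value kind.
#' @param stress Numeric vector, strictly monotone, same length; defaults to
#'   ranks `1..n`.
#' @param direction `"toward_transition"` (stress order runs toward the
#'   tipping point) or `"away"`.
#' @return A `gradient_sequence` object.
#' @export
gradient_sequence <- function(snapshots, stress = NULL,
                              direction = c("toward_transition", "away")) {
  direction <- match.arg(direction)
  if (!is.list(snapshots) || length(snapshots) < 2L) {
    abort_spatialews("Need at least two snapshots.", "validation")
  }
  lapply(snapshots, validate_grid)
  dims <- vapply(snapshots, function(g) dim(g$values), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    abort_spatialews("All snapshots must share dimensions.", "validation")
  }
  kinds <- vapply(snapshots, function(g) g$value_kind, character(1L))
  if (length(unique(kinds)) != 1L) {
    abort_spatialews("All snapshots must share value_kind.", "validation")
  }
  if (is.null(stress)) stress <- seq_along(snapshots)
  if (length(stress) != length(snapshots)) {
    abort_spatialews("`stress` must match the number of snapshots.",
                     "validation")
  }
  d <- diff(stress)
  if (!(all(d > 0) || all(d < 0))) {
    abort_spatialews("`stress` must be strictly monotone.", "validation")
  }
  structure(list(snapshots = snapshots, stress = as.numeric(stress),
                 direction = direction),
            class = "gradient_sequence")
}

#' @export
length.gradient_sequence <- function(x) length(x$snapshots)

#' @export
print.gradient_sequence <- function(x, ...) {
  d <- dim(x$snapshots[[1L]]$values)
  cat(sprintf("<gradient_sequence> %d snapshots of %d x %d (%s), stress %s to %s, %s\n",
              length(x$snapshots), d[1L], d[2L],
              x$snapshots[[1L]]$value_kind,
              format(x$stress[1L]), format(x$stress[length(x$stress)]),
              x$direction))
  invisible(x)
}

# internal: condition helper shared across modules
abort_spatialews <- function(msg, class) {
  rlang::abort(msg, class = paste0("spatialews_error_", class))
}
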