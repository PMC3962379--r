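# Independent brute-force oracles used to validate the package's fast paths.
# These deliberately share no code with the implementation.

# Moran's I by direct double sum over all ordered cell pairs.
morans_oracle <- function(vals, lag = 1L, weights = "rook",
                          boundary = "open") {
  nr <- nrow(vals); nc <- ncol(vals)
  z <- vals - mean(vals)
  num <- 0; w_tot <- 0
  for (i1 in seq_len(nr)) for (j1 in seq_len(nc)) {
    for (i2 in seq_len(nr)) for (j2 in seq_len(nc)) {
      di <- i2 - i1; dj <- j2 - j1
      if (boundary == "periodic") {
        di <- min(abs(di), nr - abs(di))
        dj <- min(abs(dj), nc - abs(dj))
      } else {
        di <- abs(di); dj <- abs(dj)
      }
      d <- if (weights == "rook") di + dj else max(di, dj)
      if (d == lag) {
        num <- num + z[i1, j1] * z[i2, j2]
        w_tot <- w_tot + 1
      }
    }
  }
  (nr * nc / w_tot) * num / sum(z^2)
}

# Connected components by BFS flood fill.
flood_fill_sizes <- function(fg, connectivity = 4L, boundary = "open") {
  nr <- nrow(fg); nc <- ncol(fg)
  seen <- matrix(FALSE, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  sizes <- integer(0)
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!fg[si, sj] || seen[si, sj]) next
    queue <- list(c(si, sj)); seen[si, sj] <- TRUE; size <- 0L
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]; size <- size + 1L
      for (o in offs) {
        i <- cur[1L] + o[1L]; j <- cur[2L] + o[2L]
        if (boundary == "periodic") {
          i <- ((i - 1L) %% nr) + 1L; j <- ((j - 1L) %% nc) + 1L
        } else if (i < 1L || i > nr || j < 1L || j > nc) next
        if (fg[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Kendall tau-b by O(n^2) pair counting with tie correction.
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# small random occupancy grid helper
random_occupancy <- function(nr, nc, p = 0.4) {
  spatial_grid(matrix(rbinom(nr * nc, 1, p), nr, nc),
               value_kind = "discrete_occupancy")
}

# TRUE when gaps appear before some labyrinth which appears before some spots
has_morphology_sequence <- function(classes) {
  gi <- which(classes == "gaps")
  if (length(gi) == 0L) return(FALSE)
  li <- which(classes == "labyrinth" & seq_along(classes) > min(gi))
  if (length(li) == 0L) return(FALSE)
  any(classes == "spots" & seq_along(classes) > min(li))
}
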