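#' Quasi-potential landscape over a gene-pair projection
#'
#' Reconstructs the quasi-potential `U(x) = -log p(x)` from a snapshot
#' ensemble: a 2-D Gaussian product KDE (Silverman bandwidths) of the
#' selected species pair, evaluated on a regular grid covering the data
#' range padded by 3 bandwidths, with the density floored at
#' `floor_frac * max(p)` so the potential stays finite. Under additive
#' noise the quasi-potential coincides with the true potential of the
#' deterministic dynamics; with the multiplicative (propensity-scaled)
#' noise of the chemical Langevin regime it is a faithful description of
#' where cells accumulate, not of the deterministic vector field.
#'
#' @param data a `snapshot_dataset`, or directly an n x 2 matrix of points.
#' @param dims species pair to project on (default the fate-defining
#'   `(Nanog, Gata6)` pair).
#' @param time_sel `"final"` (stationary reading of the snapshot ensemble),
#'   `"pooled"` (all time points) or a time index.
#' @param grid_n grid nodes per axis.
#' @param floor_frac density floor as a fraction of the density maximum.
#' @param bandwidth optional fixed per-axis KDE bandwidths overriding the
#'   Silverman rule.
#' @return object of class `landscape_grid`: `x`, `y`, `U` (grid_n x
#'   grid_n, `U[i, j]` at `(x[i], y[j])`), `bandwidths`, `floor`, `dims`,
#'   `time_sel`.
#' @export
#' @examples
#' pts <- matrix(rnorm(400), ncol = 2)
#' L <- quasipotential(pts, grid_n = 40)
#' L$U[1, 1] >= min(L$U)
quasipotential <- function(data, dims = c("Nanog", "Gata6"),
                           time_sel = "final", grid_n = 80,
                           floor_frac = 1e-12, bandwidth = NULL) {
  if (inherits(data, "snapshot_dataset")) {
    if (!all(dims %in% data$species))
      stop("unknown species: ", paste(setdiff(dims, data$species),
                                      collapse = ", "))
    T <- dim(data$values)[2]
    ti <- if (identical(time_sel, "final")) T
          else if (identical(time_sel, "pooled")) seq_len(T)
          else as.integer(time_sel)
    pts <- do.call(rbind, lapply(ti, function(t)
      cbind(data$values[dims[1], t, ], data$values[dims[2], t, ])))
  } else {
    pts <- as.matrix(data)
    if (ncol(pts) != 2) stop("point input must have 2 columns")
  }
  if (nrow(pts) < 10) stop("need at least 10 points for a landscape")
  h <- if (is.null(bandwidth)) silverman_bandwidth(pts) else rep(bandwidth, length.out = 2)
  gx <- seq(min(pts[, 1]) - 3 * h[1], max(pts[, 1]) + 3 * h[1],
            length.out = grid_n)
  gy <- seq(min(pts[, 2]) - 3 * h[2], max(pts[, 2]) + 3 * h[2],
            length.out = grid_n)
  # product-kernel KDE on the grid: p(gx_i, gy_j)
  Kx <- dnorm(outer(gx, pts[, 1], "-") / h[1]) / h[1]
  Ky <- dnorm(outer(gy, pts[, 2], "-") / h[2]) / h[2]
  P <- (Kx %*% t(Ky)) / nrow(pts)
  floor_p <- floor_frac * max(P)
  U <- -log(pmax(P, floor_p))
  structure(list(x = gx, y = gy, U = U, bandwidths = h, floor = floor_p,
                 dims = dims, time_sel = time_sel, n_points = nrow(pts)),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape grid %dx%d over (%s, %s), U in [%.3g, %.3g]>\n",
              length(x$x), length(x$y), x$dims[1], x$dims[2],
              min(x$U), max(x$U)))
  invisible(x)
}

#' Basin assignment by steepest descent on a landscape grid
#'
#' Follows the steepest-descent 8-neighbour path from every grid node to
#' its local minimum, labelling nodes by the basin they drain into. Minima
#' are sorted by depth (lowest potential first).
#'
#' @param grid a `landscape_grid`.
#' @return list with `labels` (integer matrix, same shape as `U`; label k
#'   drains to `minima[k, ]`) and `minima` (data frame: grid indices,
#'   coordinates and potential, sorted by depth).
#' @export
basin_assign <- function(grid) {
  U <- grid$U
  nr <- nrow(U); nc <- ncol(U)
  # watershed flooding: visit nodes by increasing potential; a node with no
  # already-flooded neighbour opens a new basin (a local minimum), otherwise
  # it drains into the basin of its lowest flooded neighbour. Equal-value
  # plateaus attach to the basin reached first, so a flat density-floor
  # region never spawns spurious minima.
  ord <- order(U, seq_along(U))
  labels <- matrix(NA_integer_, nr, nc)
  roots <- integer(0)
  for (node in ord) {
    i <- ((node - 1L) %% nr) + 1L
    j <- ((node - 1L) %/% nr) + 1L
    best_lab <- NA_integer_
    best_u <- Inf
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      lb <- labels[ii, jj]
      if (!is.na(lb) && U[ii, jj] < best_u) { best_u <- U[ii, jj]; best_lab <- lb }
    }
    if (is.na(best_lab)) {
      roots <- c(roots, node)
      labels[node] <- length(roots)
    } else labels[node] <- best_lab
  }
  minima <- data.frame(
    i = ((roots - 1L) %% nr) + 1L,
    j = ((roots - 1L) %/% nr) + 1L)
  minima$x <- grid$x[minima$i]
  minima$y <- grid$y[minima$j]
  minima$U <- U[cbind(minima$i, minima$j)]
  ord <- order(minima$U)
  minima <- minima[ord, , drop = FALSE]
  rownames(minima) <- NULL
  relabel <- match(seq_along(roots), ord)
  labels[] <- relabel[labels]
  list(labels = labels, minima = minima)
}

#' Count wells of a landscape above a prominence floor
#'
#' Basins whose minimum lies well below the density floor plateau are
#' counted as wells; the floor region itself is flat and forms no minima.
#'
#' @param grid `landscape_grid`.
#' @return number of basins.
#' @export
n_wells <- function(grid) {
  nrow(basin_assign(grid)$minima)
}

#' Export a landscape grid as delimited text
#'
#' Long-format `x, y, U` rows consumable by any plotting tool.
#'
#' @param grid `landscape_grid`.
#' @param path output path.
#' @export
write_landscape <- function(grid, path) {
  df <- expand.grid(x = grid$x, y = grid$y)
  df$U <- as.vector(grid$U)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
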