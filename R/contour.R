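#' (MSD, V) contour map
#'
#' Kernel-smoothed density of the per-window summaries on log-log axes:
#' x = log10(mean R2), y = log10(V). When a molecule repeatedly visits one
#' membrane environment, the environment's characteristic (MSD, V)
#' signature concentrates density and forms a peak at the corresponding
#' position, so distinct diffusion states appear as distinct peaks.
#'
#' Bandwidths default to Scott's rule per axis on the log grid
#' (`sd * n^(-1/6)`). Windows with non-positive V (degenerate, e.g.
#' constant R2) are dropped with a warning. The returned density is
#' normalized to integrate to 1 over the grid.
#'
#' @param stats a [segment_stats()] tibble; at least 10 windows.
#' @param n_grid grid cells per axis.
#' @param bandwidth optional length-2 kernel standard deviations
#'   (log10 units) for x and y.
#' @param lims optional `c(xmin, xmax, ymin, ymax)` in log10 units.
#' @return an object of class `contour_map`: list with grid vectors `x`,
#'   `y` (log10 units), density matrix `z`, `bandwidth`, and `n` (windows
#'   used).
#' @export
contour_map <- function(stats, n_grid = 64, bandwidth = NULL, lims = NULL) {
  ok <- is.finite(stats$mean_R2) & stats$mean_R2 > 0 &
    is.finite(stats$V) & stats$V > 0
  if (sum(ok) < nrow(stats))
    warning(sum(!ok), " window(s) with non-positive mean_R2 or V dropped")
  if (sum(ok) < 10) stop("need at least 10 usable windows", call. = FALSE)
  lx <- log10(stats$mean_R2[ok]); ly <- log10(stats$V[ok])
  n <- length(lx)
  if (is.null(bandwidth)) {
    bandwidth <- c(sd(lx), sd(ly)) * n^(-1 / 6)     # Scott's rule, 2D
    bandwidth <- pmax(bandwidth, 1e-3)              # degenerate clouds
  }
  if (is.null(lims))
    lims <- c(range(lx) + c(-3, 3) * bandwidth[1],
              range(ly) + c(-3, 3) * bandwidth[2])
  # MASS::kde2d uses a kernel sd of h/4
  kd <- MASS::kde2d(lx, ly, h = 4 * bandwidth, n = n_grid, lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * cell)
  structure(list(x = kd$x, y = kd$y, z = z, bandwidth = bandwidth, n = n),
            class = "contour_map")
}

#' @export
print.contour_map <- function(x, ...) {
  cat(sprintf("<contour_map> %dx%d grid over log10(mean_R2) in [%.2f, %.2f], log10(V) in [%.2f, %.2f]; %d windows\n",
              length(x$x), length(x$y), min(x$x), max(x$x), min(x$y), max(x$y), x$n))
  invisible(x)
}

#' Find density peaks in a contour map
#'
#' Identifies local maxima of the smoothed density and scores each by its
#' topographic prominence (the drop from the peak to the highest saddle
#' connecting it to any higher peak, computed by watershed-style
#' union-find over grid cells sorted by height). Peaks below
#' `min_prominence * max(z)` are discarded; of any two peaks closer than
#' `min_separation` (log10 units, either axis) only the higher survives.
#' Peak coordinates are refined off-grid by one-dimensional quadratic
#' interpolation per axis and reported on the linear scale.
#'
#' @param map a [contour_map()] object.
#' @param min_separation minimum peak separation in log10 units.
#' @param min_prominence prominence threshold as a fraction of the global
#'   density maximum.
#' @return a tibble `mean_R2` (um^2), `V`, `height`, `prominence`, sorted
#'   by height; empty if nothing qualifies.
#' @export
find_peaks <- function(map, min_separation = 0.2, min_prominence = 0.05) {
  z <- map$z; nx <- nrow(z); ny <- ncol(z)
  ord <- order(z, decreasing = TRUE)
  comp <- integer(nx * ny)                 # 0 = not yet activated
  peak_of <- integer(0)                    # component -> cell index of its peak
  prom <- numeric(0)                       # prominence when merged (NA = open)
  parent <- integer(0)
  findroot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (cell in ord) {
    ix <- (cell - 1L) %% nx + 1L; iy <- (cell - 1L) %/% nx + 1L
    nb <- c(if (ix > 1) cell - 1L, if (ix < nx) cell + 1L,
            if (iy > 1) cell - nx, if (iy < ny) cell + nx)
    roots <- unique(vapply(nb[comp[nb] > 0L], function(n) findroot(comp[n]), integer(1)))
    if (length(roots) == 0) {              # new peak
      parent <- c(parent, length(parent) + 1L)
      peak_of <- c(peak_of, cell)
      prom <- c(prom, NA_real_)
      comp[cell] <- length(parent)
    } else if (length(roots) == 1) {
      comp[cell] <- roots
    } else {                               # saddle: merge into the highest
      hts <- z[peak_of[roots]]
      win <- roots[which.max(hts)]
      for (r in roots[roots != win]) {
        prom[r] <- z[peak_of[r]] - z[cell]
        parent[r] <- win
      }
      comp[cell] <- win
    }
  }
  open <- which(is.na(prom))
  prom[open] <- z[peak_of[open]]           # global maxima: full height
  keep <- prom >= min_prominence * max(z)
  if (!any(keep))
    return(tibble(mean_R2 = numeric(), V = numeric(),
                  height = numeric(), prominence = numeric()))
  cells <- peak_of[keep]; promk <- prom[keep]
  o <- order(z[cells], decreasing = TRUE)
  cells <- cells[o]; promk <- promk[o]
  # greedy non-maximum suppression by separation
  px <- map$x[(cells - 1L) %% nx + 1L]; py <- map$y[(cells - 1L) %/% nx + 1L]
  sel <- logical(length(cells))
  for (i in seq_along(cells)) {
    if (!any(sel & abs(px - px[i]) < min_separation &
               abs(py - py[i]) < min_separation)) sel[i] <- TRUE
  }
  cells <- cells[sel]; promk <- promk[sel]
  refine <- function(ix, iy) {
    qx <- if (ix > 1 && ix < nx) {
      num <- z[ix - 1, iy] - z[ix + 1, iy]
      den <- z[ix - 1, iy] - 2 * z[ix, iy] + z[ix + 1, iy]
      if (den < 0) 0.5 * num / den else 0
    } else 0
    qy <- if (iy > 1 && iy < ny) {
      num <- z[ix, iy - 1] - z[ix, iy + 1]
      den <- z[ix, iy - 1] - 2 * z[ix, iy] + z[ix, iy + 1]
      if (den < 0) 0.5 * num / den else 0
    } else 0
    c(map$x[ix] + qx * diff(map$x[1:2]), map$y[iy] + qy * diff(map$y[1:2]))
  }
  coords <- t(vapply(cells, function(cl)
    refine((cl - 1L) %% nx + 1L, (cl - 1L) %/% nx + 1L), numeric(2)))
  tibble(mean_R2 = 10^coords[, 1], V = 10^coords[, 2],
         height = z[cells], prominence = promk)
}
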