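#' Select a species' background region by distance buffer
#'
#' The background is every study-area cell whose center lies within
#' `buffer_km` of any presence cell of either period, approximating the area a
#' species could plausibly have reached by dispersal. The default buffer is
#' 500 km.
#'
#' @param occ_hist,occ_curr occurrence data frames with `x_km`, `y_km`
#'   (and usually `cell_id`).
#' @param grid study-area cell table with `cell_id`, `x_km`, `y_km` (a climate
#'   grid works directly).
#' @param buffer_km buffer radius in km, > 0.
#' @return the rows of `grid` inside the buffer.
#' @export
select_background <- function(occ_hist, occ_curr, grid, buffer_km = 500) {
  stopifnot(buffer_km > 0, nrow(occ_hist) >= 1, nrow(occ_curr) >= 1)
  pres <- rbind(occ_hist[c("x_km", "y_km")], occ_curr[c("x_km", "y_km")])
  d <- cross_dist(as.matrix(grid[c("x_km", "y_km")]), as.matrix(pres))
  keep <- apply(d, 1, min) <= buffer_km
  bg <- grid[keep, , drop = FALSE]
  if (nrow(bg) < 20) {
    warnf("background has only %d cells; kernel density will be unstable",
          nrow(bg))
  }
  bg
}

# Gaussian product-kernel density of 2-D points evaluated on a lattice.
# Returns an R_x x R_y matrix: rows index gx, columns gy.
kde_lattice <- function(pts, gx, gy, hx, hy) {
  Kx <- stats::dnorm(outer(gx, pts[, 1], "-") / hx)
  Ky <- stats::dnorm(outer(gy, pts[, 2], "-") / hy)
  (Kx %*% t(Ky)) / (nrow(pts) * hx * hy)
}

silverman_bw <- function(x, what) {
  if (stats::sd(x) == 0) {
    stopf("%s are degenerate (zero variance) along one axis; cannot form a kernel density", what)
  }
  stats::bw.nrd0(x)
}

#' Availability-corrected kernel density surface
#'
#' Estimates the Gaussian-kernel density of occurrence points and of the
#' available background on a regular 2-D lattice, then corrects occupancy for
#' availability by dividing the occurrence density by the background density.
#' Background cells whose density falls below the truncation quantile of the
#' positive background densities are treated as unavailable (corrected density
#' 0 there), and the corrected surface is renormalized to total mass 1. The
#' same routine serves geographic space (km coordinates) and climate space
#' (PCA axes); nothing in it depends on which space is in use.
#'
#' @param points n x 2 matrix/data frame of occurrence coordinates (n >= 20;
#'   the conventional floor for stable niche estimation).
#' @param background m x 2 matrix/data frame of available-cell coordinates
#'   (m >= 20).
#' @param R lattice resolution per axis (default 100).
#' @param lattice optional list(gx, gy) of lattice node coordinates; when
#'   several surfaces must share a lattice (two periods, regional vs global),
#'   build it once with [make_lattice()] and pass it to every call.
#' @param trunc_quantile quantile (of positive background densities) below
#'   which background is deemed unavailable (default 0.01).
#' @param min_points occurrence floor (default 20).
#' @return object of class `density_surface`: lattice axes, occurrence
#'   density, background density, corrected density `z` (sums to 1),
#'   occupancy mask (`z > 0`), bandwidths, truncation threshold.
#' @export
estimate_density <- function(points, background, R = 100, lattice = NULL,
                             trunc_quantile = 0.01, min_points = 20) {
  points <- as.matrix(as.data.frame(points))
  background <- as.matrix(as.data.frame(background))
  if (nrow(points) < min_points) {
    stopf("need at least %d occurrence points, got %d", min_points, nrow(points))
  }
  if (nrow(background) < 20) {
    stopf("need at least 20 background cells, got %d", nrow(background))
  }
  if (stats::sd(points[, 1]) == 0 && stats::sd(points[, 2]) == 0) {
    stopf("all occurrence points are coincident; zero-variance kernel density")
  }
  hx_b <- silverman_bw(background[, 1], "background cells")
  hy_b <- silverman_bw(background[, 2], "background cells")
  # point bandwidths fall back to the background rule if one axis is flat
  hx_p <- if (stats::sd(points[, 1]) > 0) stats::bw.nrd0(points[, 1]) else hx_b
  hy_p <- if (stats::sd(points[, 2]) > 0) stats::bw.nrd0(points[, 2]) else hy_b
  if (is.null(lattice)) {
    lattice <- make_lattice(background, R, margin = c(hx_b / 2, hy_b / 2))
  }
  gx <- lattice$gx
  gy <- lattice$gy
  occ_d <- kde_lattice(points, gx, gy, hx_p, hy_p)
  bg_d <- kde_lattice(background, gx, gy, hx_b, hy_b)
  pos <- bg_d[bg_d > 0]
  trunc <- stats::quantile(pos, trunc_quantile, names = FALSE)
  # A Gaussian kernel is positive everywhere, so the occupied region must be
  # delimited by truncating the occurrence density as well: nodes whose
  # occurrence density falls below the trunc_quantile of the density
  # evaluated at the occurrence points themselves are treated as unoccupied.
  Kx <- stats::dnorm(outer(points[, 1], points[, 1], "-") / hx_p)
  Ky <- stats::dnorm(outer(points[, 2], points[, 2], "-") / hy_p)
  occ_at_pts <- rowSums(Kx * Ky) / (nrow(points) * hx_p * hy_p)
  occ_trunc <- stats::quantile(occ_at_pts, trunc_quantile, names = FALSE)
  z <- ifelse(bg_d > trunc & occ_d >= occ_trunc, occ_d / bg_d, 0)
  total <- sum(z)
  if (total == 0) stopf("corrected density is identically zero after truncation")
  z <- z / total
  structure(list(
    gx = gx, gy = gy,
    occ_density = occ_d, bg_density = bg_d,
    z = z, mask = z > 0, avail = bg_d > trunc,
    bw_points = c(hx_p, hy_p), bw_background = c(hx_b, hy_b),
    trunc = trunc, occ_trunc = occ_trunc, trunc_quantile = trunc_quantile,
    R = length(gx)
  ), class = "density_surface")
}

#' Build a shared density lattice from a set of coordinates
#'
#' The lattice spans the coordinates' bounding box plus a margin (typically
#' half a bandwidth per axis).
#'
#' @param coords matrix/data frame of 2-D coordinates.
#' @param R nodes per axis.
#' @param margin length-2 numeric margin added on both sides of each axis.
#' @return list(gx, gy).
#' @export
make_lattice <- function(coords, R = 100, margin = c(0, 0)) {
  coords <- as.matrix(as.data.frame(coords))
  list(
    gx = seq(min(coords[, 1]) - margin[1], max(coords[, 1]) + margin[1],
             length.out = R),
    gy = seq(min(coords[, 2]) - margin[2], max(coords[, 2]) + margin[2],
             length.out = R)
  )
}

# Low-level constructor used by tests and by the null model: wrap an already
# normalized corrected-density matrix as a density_surface.
#' Construct a density surface from an explicit corrected-density matrix
#'
#' Mostly useful for tests and for hand-built examples; `z` is renormalized to
#' sum 1 and the occupancy mask is `z > 0`.
#'
#' @param z matrix of nonnegative densities (rows = gx, cols = gy).
#' @param gx,gy lattice node coordinates (defaults: unit spacing).
#' @param avail logical availability matrix (default: all TRUE).
#' @return a `density_surface`.
#' @export
density_surface <- function(z, gx = seq_len(nrow(z)), gy = seq_len(ncol(z)),
                            avail = NULL) {
  z <- as.matrix(z)
  stopifnot(all(z >= 0), sum(z) > 0)
  z <- z / sum(z)
  structure(list(
    gx = gx, gy = gy, occ_density = z, bg_density = NULL,
    z = z, mask = z > 0,
    avail = if (is.null(avail)) matrix(TRUE, nrow(z), ncol(z)) else avail,
    bw_points = c(NA, NA), bw_background = c(NA, NA),
    trunc = 0, trunc_quantile = NA_real_, R = length(gx)
  ), class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("density_surface: %d x %d lattice, mass %.6f, %d occupied nodes\n",
              length(x$gx), length(x$gy), sum(x$z), sum(x$mask)))
  invisible(x)
}

same_lattice <- function(z1, z2) {
  isTRUE(all.equal(z1$gx, z2$gx)) && isTRUE(all.equal(z1$gy, z2$gy))
}

check_lattice <- function(z1, z2) {
  if (!same_lattice(z1, z2)) {
    stopf(paste0("density surfaces are on different lattices: ",
                 "[%d x %d, x %.3f..%.3f, y %.3f..%.3f] vs ",
                 "[%d x %d, x %.3f..%.3f, y %.3f..%.3f]"),
          length(z1$gx), length(z1$gy), min(z1$gx), max(z1$gx),
          min(z1$gy), max(z1$gy),
          length(z2$gx), length(z2$gy), min(z2$gx), max(z2$gx),
          min(z2$gy), max(z2$gy))
  }
  invisible(TRUE)
}
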