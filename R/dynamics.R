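#' Schoener's D overlap between two density surfaces
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over a common lattice; 0 means disjoint
#' surfaces, 1 identical surfaces. Symmetric in its arguments.
#'
#' @param z1,z2 `density_surface` objects on the same lattice.
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(z1, z2) {
  check_lattice(z1, z2)
  1 - 0.5 * sum(abs(z1$z - z2$z))
}

# Raw (unstandardized) partition masses between two corrected surfaces given
# their occupancy masks. S* averages the two periods' shared-region masses so
# the single stability value is symmetric between periods.
partition_masses <- function(z1, m1, z2, m2) {
  shared <- m1 & m2
  list(
    U = sum(z1[m1 & !m2]),
    S = (sum(z1[shared]) + sum(z2[shared])) / 2,
    E = sum(z2[m2 & !m1])
  )
}

#' Unfilling / stability / expansion partition of two density surfaces
#'
#' Partitions the occurrence-density mass into the region occupied only
#' historically (unfilling U), occupied in both periods (stability S) and
#' occupied only currently (expansion E), then standardizes so U + S + E = 1.
#' With an analogue mask (climate space), the partition is computed inside the
#' mask only, and the mass outside it is reported as niche abandonment `A_n`
#' (historical mass in climates with no current analogue) and niche pioneering
#' `P_n` (current mass in climates with no historical analogue); A_n and P_n
#' are excluded from the U/S/E standardization.
#'
#' @param z1 historical `density_surface`.
#' @param z2 current `density_surface`.
#' @param analogue optional logical lattice mask from [analogue_mask()].
#' @return named list: `U`, `S`, `E` (and `A_n`, `P_n` when `analogue` given).
#' @export
dynamics_partition <- function(z1, z2, analogue = NULL) {
  check_lattice(z1, z2)
  za <- z1$z
  zb <- z2$z
  ma <- z1$mask
  mb <- z2$mask
  out <- list()
  if (!is.null(analogue)) {
    stopifnot(identical(dim(analogue), dim(za)))
    out$A_n <- sum(za[!analogue])
    out$P_n <- sum(zb[!analogue])
    za <- ifelse(analogue, za, 0)
    zb <- ifelse(analogue, zb, 0)
    ma <- ma & analogue
    mb <- mb & analogue
  }
  p <- partition_masses(za, ma, zb, mb)
  total <- p$U + p$S + p$E
  if (total == 0) {
    stopf("both surfaces carry zero mass after truncation%s; cannot partition",
          if (is.null(analogue)) "" else " inside the analogue mask")
  }
  c(list(U = p$U / total, S = p$S / total, E = p$E / total), out)
}

#' Analogue-climate mask
#'
#' A lattice node is analogue climate when both periods' availability
#' (background-density above truncation) holds there; occupied non-analogue
#' mass defines niche abandonment and pioneering.
#'
#' @param z1,z2 per-period `density_surface` objects carrying availability.
#' @return logical matrix over the shared lattice.
#' @export
analogue_mask <- function(z1, z2) {
  check_lattice(z1, z2)
  mask <- z1$avail & z2$avail
  if (!any(mask)) stopf("no shared (analogue) climate between the two periods")
  mask
}

#' Range centroid shift between two occurrence grids
#'
#' Centroids are unweighted means of occupied cell centers (optionally
#' density-weighted). The bearing is measured clockwise from grid north (+y)
#' in `[0, 360)`; it is `NA` when the displacement is zero.
#'
#' @param occ1,occ2 occurrence data frames with `x_km`, `y_km`.
#' @param weights1,weights2 optional per-cell weights for density-weighted
#'   centroids.
#' @return list(distance_km, bearing_deg).
#' @export
centroid_shift <- function(occ1, occ2, weights1 = NULL, weights2 = NULL) {
  stopifnot(nrow(occ1) >= 1, nrow(occ2) >= 1)
  cen <- function(occ, w) {
    if (is.null(w)) {
      c(mean(occ$x_km), mean(occ$y_km))
    } else {
      c(sum(occ$x_km * w) / sum(w), sum(occ$y_km * w) / sum(w))
    }
  }
  d <- cen(occ2, weights2) - cen(occ1, weights1)
  dist <- sqrt(sum(d^2))
  bearing <- if (dist == 0) NA_real_ else (atan2(d[1], d[2]) * 180 / pi) %% 360
  list(distance_km = dist, bearing_deg = bearing)
}

#' Full per-species shift analysis in one space
#'
#' Convenience wrapper: builds a shared lattice over the pooled background,
#' estimates both periods' availability-corrected surfaces, and returns
#' Schoener's D, the standardized dynamics partition (analogue-restricted in
#' climate space) and, in geographic space, the centroid shift.
#'
#' @param occ1,occ2 n x 2 coordinate tables (geographic km or climate scores)
#'   of the two periods' presences.
#' @param bg1,bg2 background coordinates per period (identical in geographic
#'   space; per-period climate scores of the same background cells in climate
#'   space).
#' @param space `"geographic"` or `"climate"`.
#' @param R lattice resolution.
#' @param trunc_quantile availability truncation quantile.
#' @return list with elements `D`, `U`, `S`, `E`, (`A_n`, `P_n` in climate
#'   space), (`centroid_shift_km`, `bearing_deg` in geographic space), and the
#'   two surfaces.
#' @export
shift_analysis <- function(occ1, occ2, bg1, bg2 = bg1,
                           space = c("geographic", "climate"),
                           R = 100, trunc_quantile = 0.01) {
  space <- match.arg(space)
  pooled_bg <- rbind(as.data.frame(bg1), as.data.frame(bg2))
  h <- c(stats::bw.nrd0(pooled_bg[[1]]), stats::bw.nrd0(pooled_bg[[2]]))
  lattice <- make_lattice(pooled_bg, R, margin = h / 2)
  z1 <- estimate_density(occ1, bg1, R = R, lattice = lattice,
                         trunc_quantile = trunc_quantile)
  z2 <- estimate_density(occ2, bg2, R = R, lattice = lattice,
                         trunc_quantile = trunc_quantile)
  out <- list(space = space, z1 = z1, z2 = z2, D = schoener_d(z1, z2))
  if (space == "climate") {
    mask <- analogue_mask(z1, z2)
    out <- c(out, dynamics_partition(z1, z2, analogue = mask))
    out$analogue <- mask
  } else {
    out <- c(out, dynamics_partition(z1, z2))
    occ1 <- as.data.frame(occ1)
    occ2 <- as.data.frame(occ2)
    names(occ1)[1:2] <- names(occ2)[1:2] <- c("x_km", "y_km")
    cs <- centroid_shift(occ1, occ2)
    out$centroid_shift_km <- cs$distance_km
    out$bearing_deg <- cs$bearing_deg
  }
  out
}
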