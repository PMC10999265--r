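#' Compute the 19 bioclimatic variables from one year of monthly climate
#'
#' Summarises 12 months of mean/min/max temperature and precipitation into the
#' standard BIO1..BIO19 variables. Quarters are any 3 consecutive months with
#' December-January wraparound; ties between candidate quarters are broken by
#' the earliest starting month. BIO4 is the (n-1)-denominator standard
#' deviation of monthly mean temperature times 100; BIO15 is the coefficient
#' of variation of monthly precipitation (sd/mean * 100), with the denominator
#' replaced by 1 only when the mean is exactly 0.
#'
#' @param tmean,tmin,tmax numeric length-12 monthly temperatures (degrees C).
#' @param prec numeric length-12 monthly precipitation (mm).
#' @return named numeric vector `bio1` .. `bio19`.
#' @export
compute_bioclim <- function(tmean, tmin, tmax, prec) {
  for (nm in c("tmean", "tmin", "tmax", "prec")) {
    x <- get(nm)
    if (length(x) != 12) {
      stopf("%s must have 12 monthly values, got %d", nm, length(x))
    }
    if (anyNA(x)) {
      stopf("%s is missing for month(s) %s", nm,
            paste(which(is.na(x)), collapse = ", "))
    }
  }
  # quarter summaries: start month 1..12, wrapping across Dec-Jan
  qmonths <- function(m) ((m - 1):(m + 1)) %% 12 + 1
  qt <- vapply(1:12, function(m) mean(tmean[qmonths(m)]), numeric(1))
  qp <- vapply(1:12, function(m) sum(prec[qmonths(m)]), numeric(1))
  wettest <- which.max(qp) # which.max/min take the first -> earliest start
  driest  <- which.min(qp)
  warmest <- which.max(qt)
  coldest <- which.min(qt)

  p_mean <- mean(prec)
  out <- c(
    bio1  = mean(tmean),
    bio2  = mean(tmax - tmin),
    bio3  = NA_real_, # filled below (needs bio7)
    bio4  = stats::sd(tmean) * 100,
    bio5  = max(tmax),
    bio6  = min(tmin),
    bio7  = max(tmax) - min(tmin),
    bio8  = qt[wettest],
    bio9  = qt[driest],
    bio10 = qt[warmest],
    bio11 = qt[coldest],
    bio12 = sum(prec),
    bio13 = max(prec),
    bio14 = min(prec),
    bio15 = stats::sd(prec) / (if (p_mean == 0) 1 else p_mean) * 100,
    bio16 = qp[wettest],
    bio17 = qp[driest],
    bio18 = qp[warmest],
    bio19 = qp[coldest]
  )
  out["bio3"] <- if (out["bio7"] == 0) 0 else out["bio2"] / out["bio7"] * 100
  out
}

#' Average yearly bioclim tables over the years of each study period
#'
#' @param yearly data frame with columns `cell_id`, `year`, `bio1`..`bio19`
#'   (one row per cell and year).
#' @param periods named list of integer year vectors, e.g.
#'   `list(historical = 1984:1988, current = 2012:2017)`.
#' @return named list of climate grids (one data frame per period, columns
#'   `cell_id`, `bio1`..`bio19`, plus any coordinate columns present in
#'   `yearly`), each the per-cell arithmetic mean over the period's years.
#' @export
average_periods <- function(yearly, periods) {
  stopifnot(is.data.frame(yearly), length(periods) >= 1)
  vars <- intersect(bio_names(), names(yearly))
  coord <- intersect(c("x_km", "y_km"), names(yearly))
  lapply(periods, function(yrs) {
    missing <- setdiff(yrs, unique(yearly$year))
    if (length(missing)) {
      stopf("years missing from yearly table: %s",
            paste(missing, collapse = ", "))
    }
    sub <- yearly[yearly$year %in% yrs, , drop = FALSE]
    agg <- stats::aggregate(sub[vars], by = list(cell_id = sub$cell_id), mean)
    if (length(coord)) {
      xy <- unique(sub[c("cell_id", coord)])
      agg <- merge(xy, agg, by = "cell_id", sort = TRUE)
    }
    agg[order(agg$cell_id), , drop = FALSE]
  })
}

#' Buffer-averaged climate around points
#'
#' For each point, averages each bioclim variable over all grid cells whose
#' centers lie within `radius_km` (inclusive). Emulates extraction of climate
#' around survey-route centroids.
#'
#' @param points data frame with columns `point_id`, `x_km`, `y_km`.
#' @param radius_km buffer radius, km, > 0.
#' @param grid climate grid data frame (`cell_id`, `x_km`, `y_km`,
#'   `bio1`..`bio19`).
#' @return data frame `point_id` + averaged bioclim columns.
#' @export
buffer_extract <- function(points, radius_km, grid) {
  stopifnot(radius_km > 0)
  vars <- intersect(bio_names(), names(grid))
  d <- cross_dist(as.matrix(points[c("x_km", "y_km")]),
                  as.matrix(grid[c("x_km", "y_km")]))
  out <- lapply(seq_len(nrow(points)), function(i) {
    inside <- d[i, ] <= radius_km
    if (!any(inside)) {
      stopf("point '%s' has no grid cell center within %g km",
            points$point_id[i], radius_km)
    }
    colMeans(grid[inside, vars, drop = FALSE])
  })
  cbind(data.frame(point_id = points$point_id), do.call(rbind, out))
}
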