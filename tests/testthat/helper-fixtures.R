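# Shared fixtures, built in code at test time.

bios <- paste0("bio", 1:19)

# A small shifted-gradient landscape + one virtual species, run through the
# climate-space shift analysis. Used by the mechanism tests.
climate_space_dynamics <- function(seed, dispersal = Inf, persistence = 0,
                                   detection = 1, R = 100) {
  scn <- landscape_scenario(seed = derive_seed(seed, "land"))
  clim <- generate_landscape(scn)
  sp <- species_scenario(
    optimum = c(bio1 = 7, bio12 = 600),
    tolerance = c(bio1 = 1.5, bio12 = 150),
    dispersal_limit_km = dispersal, persistence_prob = persistence,
    detection_prob = detection, seed = derive_seed(seed, "occ"))
  occ <- generate_occupancy(sp, clim$period1, clim$period2)
  bg <- select_background(occ$period1, occ$period2, clim$period1, 500)
  bg2 <- clim$period2[match(bg$cell_id, clim$period2$cell_id), , drop = FALSE]
  pca <- suppressWarnings(fit_pca(rbind(bg[bios], bg2[bios])))
  s_bg1 <- project_pca(pca, bg[bios])
  s_bg2 <- project_pca(pca, bg2[bios])
  s1 <- s_bg1[match(occ$period1$cell_id, bg$cell_id), , drop = FALSE]
  s2 <- s_bg2[match(occ$period2$cell_id, bg$cell_id), , drop = FALSE]
  shift_analysis(s1, s2, s_bg1, s_bg2, space = "climate", R = R)
}

# A compact elliptical occurrence patch at a random position on a static
# landscape; patches from independent seeds are independent random
# placements, which is what the null-model calibration needs.
static_patch_world <- function() {
  scn <- landscape_scenario(nx = 30, ny = 30, cell_size_km = 50,
                            delta = c(bio1 = 0, bio12 = 0),
                            noise_sd = c(bio1 = 0, bio12 = 0), seed = 1)
  generate_landscape(scn)
}

draw_patch <- function(clim, seed) {
  r <- function(v, p) quantile(clim$period1[[v]], p, names = FALSE)
  for (attempt in 1:50) {
    set.seed(derive_seed(seed, "patch", attempt))
    opt <- c(bio1 = runif(1, r("bio1", 0), r("bio1", 1)),
             bio12 = runif(1, r("bio12", 0), r("bio12", 1)))
    sp <- species_scenario(opt, tolerance = c(bio1 = 0.8, bio12 = 60),
                           seed = derive_seed(seed, "occ", attempt))
    occ <- tryCatch(generate_occupancy(sp, clim$period1, clim$period1),
                    error = function(e) NULL)
    if (!is.null(occ) && nrow(occ$period1) >= 20) return(occ$period1)
  }
  stop("could not draw a viable patch")
}

# Minimal monthly series with a single wet, warm quarter (Jun-Aug).
wet_warm_year <- function() {
  tmean <- c(0, 1, 4, 8, 13, 18, 20, 19, 14, 9, 4, 1)
  list(tmean = tmean, tmin = tmean - 5, tmax = tmean + 5,
       prec = c(30, 30, 40, 50, 60, 120, 140, 130, 60, 50, 40, 30))
}
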