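#' Landscape scenario for the two-period climate simulator
#'
#' Describes an equal-area study grid with per-variable linear spatial
#' gradients, an additive between-period change (directional climate change),
#' and i.i.d. Gaussian cell noise. Only two informative variables (a
#' temperature-like `bio1` and a precipitation-like `bio12`) vary by default;
#' the remaining 17 bioclim variables are held at plausible constants so the
#' downstream PCA stays interpretable but non-degenerate.
#'
#' @param nx,ny grid dimensions in cells (>= 10 each).
#' @param cell_size_km cell size, km (> 0).
#' @param gradient data frame `var`, `origin`, `slope_x`, `slope_y`
#'   (value at the grid origin and change per km along x / y).
#' @param delta named numeric: additive change of each gradient variable
#'   between period 1 and period 2 (variables absent here default to 0).
#' @param noise_sd named numeric: spatially uncorrelated noise sd per
#'   gradient variable (absent = 0).
#' @param constants named numeric for the non-gradient bioclim variables.
#' @param seed integer.
#' @return object of class `landscape_scenario`.
#' @export
landscape_scenario <- function(nx = 40, ny = 40, cell_size_km = 50,
                               gradient = default_gradient(),
                               delta = c(bio1 = 1, bio12 = -50),
                               noise_sd = c(bio1 = 0.1, bio12 = 5),
                               constants = default_constants(),
                               seed = 1) {
  if (nx < 10 || ny < 10) stopf("grid must be at least 10 x 10 cells (got %d x %d)", nx, ny)
  if (cell_size_km <= 0) stopf("cell_size_km must be positive")
  stopifnot(all(c("var", "origin", "slope_x", "slope_y") %in% names(gradient)))
  full_delta <- stats::setNames(rep(0, nrow(gradient)), gradient$var)
  full_delta[names(delta)] <- delta
  full_noise <- stats::setNames(rep(0, nrow(gradient)), gradient$var)
  full_noise[names(noise_sd)] <- noise_sd
  structure(list(
    nx = nx, ny = ny, cell_size_km = cell_size_km,
    gradient = gradient, delta = full_delta, noise_sd = full_noise,
    constants = constants, seed = seed
  ), class = "landscape_scenario")
}

# Default spatial structure: temperature decreases northward (~0.5 degC per
# 100 km), precipitation increases eastward; three decades of change warm
# every cell by 1 degC and dry it by 50 mm (see landscape_scenario defaults).
default_gradient <- function() {
  data.frame(
    var = c("bio1", "bio12"),
    origin = c(12, 400),
    slope_x = c(0, 0.2),
    slope_y = c(-0.005, 0)
  )
}

default_constants <- function() {
  c(bio2 = 9, bio3 = 35, bio4 = 600, bio5 = 26, bio6 = -4, bio7 = 30,
    bio8 = 14, bio9 = 2, bio10 = 17, bio11 = 0, bio13 = 80, bio14 = 20,
    bio15 = 30, bio16 = 220, bio17 = 70, bio18 = 200, bio19 = 90)
}

#' Generate two-period climate grids from a landscape scenario
#'
#' Period 1 is the deterministic gradient plus noise; period 2 adds the
#' per-variable delta and an independent noise draw. Reproducible given the
#' scenario seed.
#'
#' @param scn a `landscape_scenario`.
#' @return list of two climate grids (`period1`, `period2`), data frames with
#'   `cell_id`, `x_km`, `y_km`, `bio1`..`bio19` over identical cells.
#' @export
generate_landscape <- function(scn) {
  stopifnot(inherits(scn, "landscape_scenario"))
  cells <- expand.grid(ix = seq_len(scn$nx), iy = seq_len(scn$ny))
  x <- (cells$ix - 0.5) * scn$cell_size_km
  y <- (cells$iy - 0.5) * scn$cell_size_km
  n <- nrow(cells)
  base <- data.frame(cell_id = seq_len(n), x_km = x, y_km = y)
  for (v in bio_names()) base[[v]] <- unname(scn$constants[v])
  for (i in seq_len(nrow(scn$gradient))) {
    g <- scn$gradient[i, ]
    base[[g$var]] <- g$origin + g$slope_x * x + g$slope_y * y
  }
  set.seed(scn$seed)
  p1 <- p2 <- base
  for (v in scn$gradient$var) {
    sdv <- scn$noise_sd[v]
    p1[[v]] <- p1[[v]] + if (sdv > 0) stats::rnorm(n, 0, sdv) else 0
    p2[[v]] <- p2[[v]] + scn$delta[v] +
      if (sdv > 0) stats::rnorm(n, 0, sdv) else 0
  }
  list(period1 = p1, period2 = p2)
}

#' Species scenario for the virtual-species occupancy simulator
#'
#' @param optimum named numeric: climatic optimum (subset of bioclim
#'   variables, typically `bio1` and `bio12`).
#' @param tolerance named numeric, same variables: Gaussian niche sd (> 0).
#' @param suitability_threshold cell is suitable when Gaussian suitability
#'   is at least this (in (0, 1); default 0.5).
#' @param dispersal_limit_km maximum colonization distance from any period-1
#'   occupied cell (`Inf` = full climate tracking).
#' @param persistence_prob probability that an occupied-but-now-unsuitable
#'   cell stays occupied in period 2 (the extinction-debt knob, `[0, 1]`).
#' @param detection_prob probability a truly occupied cell is recorded
#'   (in (0, 1]).
#' @param seed integer.
#' @return object of class `species_scenario`.
#' @export
species_scenario <- function(optimum, tolerance,
                             suitability_threshold = 0.5,
                             dispersal_limit_km = Inf,
                             persistence_prob = 0,
                             detection_prob = 1,
                             seed = 1) {
  stopifnot(length(optimum) == length(tolerance),
            all(names(optimum) == names(tolerance)))
  if (any(tolerance <= 0)) stopf("tolerance must be positive elementwise")
  if (dispersal_limit_km < 0) stopf("dispersal_limit_km must be >= 0")
  if (suitability_threshold <= 0 || suitability_threshold >= 1) {
    stopf("suitability_threshold must be in (0, 1)")
  }
  if (persistence_prob < 0 || persistence_prob > 1) {
    stopf("persistence_prob must be in [0, 1]")
  }
  if (detection_prob <= 0 || detection_prob > 1) {
    stopf("detection_prob must be in (0, 1]")
  }
  structure(list(
    optimum = optimum, tolerance = tolerance,
    suitability_threshold = suitability_threshold,
    dispersal_limit_km = dispersal_limit_km,
    persistence_prob = persistence_prob,
    detection_prob = detection_prob, seed = seed
  ), class = "species_scenario")
}

# Gaussian climatic suitability of each grid cell.
suitability <- function(sp, climate) {
  q <- rep(0, nrow(climate))
  for (v in names(sp$optimum)) {
    q <- q + ((climate[[v]] - sp$optimum[v]) / sp$tolerance[v])^2
  }
  exp(-0.5 * q)
}

#' Generate two-period occupancy for a virtual species
#'
#' Period-1 occupancy is the climatically suitable cells (Gaussian
#' suitability at or above the threshold), thinned by the detection
#' probability. Period-2 occupancy is the period-2-suitable cells within the
#' dispersal limit of any (true, pre-detection) period-1 occupied cell, plus
#' period-1 occupied cells that are no longer suitable but persist with the
#' extinction-debt probability; the union is thinned by detection. Cell
#' distances are Euclidean between cell centers; the dispersal reach uses
#' `<=`. RNG consumption is per-cell and fixed-order, so results are
#' reproducible given the seed regardless of the occupancy pattern.
#'
#' @param sp a `species_scenario`.
#' @param climate1,climate2 climate grids over identical cells.
#' @param species species id attached to the output (default `"sp1"`).
#' @return list of two occurrence data frames (`period1`, `period2`) with
#'   columns `species`, `period`, `cell_id`, `x_km`, `y_km`.
#' @export
generate_occupancy <- function(sp, climate1, climate2, species = "sp1") {
  stopifnot(inherits(sp, "species_scenario"))
  if (!identical(climate1$cell_id, climate2$cell_id)) {
    stopf("the two climate grids must share the same cell set")
  }
  n <- nrow(climate1)
  suit1 <- suitability(sp, climate1) >= sp$suitability_threshold
  suit2 <- suitability(sp, climate2) >= sp$suitability_threshold
  set.seed(sp$seed)
  u_pers <- stats::runif(n)
  u_det1 <- stats::runif(n)
  u_det2 <- stats::runif(n)
  true1 <- suit1
  xy <- as.matrix(climate1[c("x_km", "y_km")])
  if (any(true1)) {
    if (is.infinite(sp$dispersal_limit_km)) {
      reachable <- rep(TRUE, n)
    } else {
      d <- cross_dist(xy, xy[true1, , drop = FALSE])
      reachable <- apply(d, 1, min) <= sp$dispersal_limit_km
    }
  } else {
    reachable <- rep(FALSE, n)
  }
  retained <- true1 & !suit2 & (u_pers <= sp$persistence_prob)
  true2 <- (suit2 & reachable) | retained
  occ1 <- true1 & (u_det1 <= sp$detection_prob)
  occ2 <- true2 & (u_det2 <= sp$detection_prob)
  if (!any(occ1)) stopf("degenerate species '%s': empty occupancy in period 1", species)
  if (!any(occ2)) stopf("degenerate species '%s': empty occupancy in period 2", species)
  mk <- function(occ, period) {
    data.frame(species = species, period = period,
               cell_id = climate1$cell_id[occ],
               x_km = climate1$x_km[occ], y_km = climate1$y_km[occ],
               stringsAsFactors = FALSE)
  }
  list(period1 = mk(occ1, "historical"), period2 = mk(occ2, "current"))
}

#' Simulate a phylogeny, trait table and phylogenetically structured response
#'
#' Simulates a constant-rate pure-birth tree scaled to root depth 1,
#' Brownian-motion traits on it (standardized; three traits coerced to
#' ordinal 1-3 by terciles: trophic level, migration, habitat openness), and
#' a response `y = X beta_true + eps` with
#' `cov(eps) = sigma2 * (lambda_true * C + (1 - lambda_true) * diag(C))`.
#'
#' @param n_species number of tips (>= 5).
#' @param beta_true named numeric of true effects on the standardized
#'   predictor scale (names among the trait columns; absent = 0).
#' @param lambda_true residual phylogenetic signal in `[0, 1]`.
#' @param residual_sd residual sd (> 0).
#' @param seed integer.
#' @return list: `tree` (`phylo`), `traits` (data frame, `species` + 8 trait
#'   columns), `X` (standardized predictor matrix), `beta_true` (full named
#'   vector), `lambda_true`, `residual_sd`, `y` (named response), `C`.
#' @export
generate_trait_set <- function(n_species, beta_true = c(hand_wing_index = 1),
                               lambda_true = 0.8, residual_sd = 1, seed = 1) {
  if (n_species < 5) stopf("need at least 5 species")
  if (lambda_true < 0 || lambda_true > 1) stopf("lambda_true must be in [0, 1]")
  if (residual_sd <= 0) stopf("residual_sd must be positive")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  C <- ape::vcv(tree)
  L <- chol(C) # C = L'L; t(L) %*% z has covariance C
  bm_trait <- function() {
    x <- drop(t(L) %*% stats::rnorm(n_species))
    (x - mean(x)) / stats::sd(x)
  }
  cont <- c("body_mass", "hand_wing_index", "range_size",
            "breeding_latitude", "niche_breadth")
  ord <- c("trophic_level", "migration", "habitat_openness")
  traits <- data.frame(species = tree$tip.label)
  for (v in cont) traits[[v]] <- bm_trait()
  for (v in ord) {
    x <- bm_trait()
    traits[[v]] <- as.integer(cut(x, stats::quantile(x, c(0, 1/3, 2/3, 1)),
                                  labels = FALSE, include.lowest = TRUE))
  }
  X <- standardize_traits(traits)
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  unknown <- setdiff(names(beta_true), names(beta))
  if (length(unknown)) stopf("unknown trait(s) in beta_true: %s",
                             paste(unknown, collapse = ", "))
  beta[names(beta_true)] <- beta_true
  Vres <- lambda_true * C + (1 - lambda_true) * diag(diag(C))
  eps <- residual_sd * drop(t(chol(Vres)) %*% stats::rnorm(n_species))
  y <- drop(X %*% beta) + eps
  names(y) <- tree$tip.label
  list(tree = tree, traits = traits, X = X, beta_true = beta,
       lambda_true = lambda_true, residual_sd = residual_sd, y = y, C = C)
}

#' Simulate a whole two-period virtual-species cohort
#'
#' Builds one landscape, a phylogeny + trait table, and per-species
#' occupancies whose dispersal limitation is driven by the hand wing index
#' (flight efficiency): dispersal limit `= 150 * exp(z_HWI)` km on the
#' standardized scale, so efficient flyers track the shifting climate while
#' poor flyers lag. Species optima are spread over the inner climate range so
#' every species has a viable range in both periods; species that come out
#' degenerate are redrawn (up to 20 attempts) with derived seeds.
#'
#' @param n_species cohort size.
#' @param scn landscape scenario (default [landscape_scenario()] defaults).
#' @param persistence_prob extinction-debt probability shared by the cohort.
#' @param detection_prob detection probability shared by the cohort.
#' @param seed integer master seed.
#' @return list: `climate` (two grids), `occurrences` (long data frame over
#'   species x period), `tree`, `traits`, `species_meta` (per-species optima
#'   and dispersal limits).
#' @export
simulate_cohort <- function(n_species = 30, scn = landscape_scenario(seed = seed),
                            persistence_prob = 0.3, detection_prob = 0.95,
                            seed = 1) {
  clim <- generate_landscape(scn)
  ts <- generate_trait_set(n_species, beta_true = c(hand_wing_index = 0),
                           lambda_true = 0.5, seed = derive_seed(seed, "traits"))
  hwi <- ts$X[, "hand_wing_index"]
  disp <- 150 * exp(hwi)
  r1 <- function(v, p) stats::quantile(clim$period1[[v]], p, names = FALSE)
  occ_list <- list()
  meta <- list()
  for (i in seq_len(n_species)) {
    id <- ts$tree$tip.label[i]
    occ <- NULL
    for (attempt in 1:20) {
      sd_i <- derive_seed(seed, "species", id, attempt)
      set.seed(sd_i)
      opt <- c(bio1 = stats::runif(1, r1("bio1", 0.3), r1("bio1", 0.7)),
               bio12 = stats::runif(1, r1("bio12", 0.3), r1("bio12", 0.7)))
      sp <- species_scenario(
        optimum = opt, tolerance = c(bio1 = 1.5, bio12 = 150),
        dispersal_limit_km = disp[i],
        persistence_prob = persistence_prob,
        detection_prob = detection_prob,
        seed = derive_seed(sd_i, "occ"))
      occ <- tryCatch(
        generate_occupancy(sp, clim$period1, clim$period2, species = id),
        error = function(e) NULL)
      if (!is.null(occ) && nrow(occ$period1) >= 20 && nrow(occ$period2) >= 20) break
      occ <- NULL
    }
    if (is.null(occ)) stopf("could not simulate a viable species for tip %s", id)
    occ_list[[id]] <- rbind(occ$period1, occ$period2)
    meta[[id]] <- data.frame(species = id, opt_bio1 = opt["bio1"],
                             opt_bio12 = opt["bio12"],
                             dispersal_limit_km = disp[i],
                             row.names = NULL)
  }
  list(
    climate = clim,
    occurrences = do.call(rbind, c(occ_list, list(make.row.names = FALSE))),
    tree = ts$tree,
    traits = ts$traits,
    species_meta = do.call(rbind, c(meta, list(make.row.names = FALSE)))
  )
}
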