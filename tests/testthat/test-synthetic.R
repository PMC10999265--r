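test_that("landscape generation honours identity, additivity and determinism", {
  scn0 <- landscape_scenario(nx = 12, ny = 12, delta = c(bio1 = 0, bio12 = 0),
                             noise_sd = c(bio1 = 0, bio12 = 0), seed = 4)
  clim0 <- generate_landscape(scn0)
  expect_equal(clim0$period1, clim0$period2)
  scn2 <- landscape_scenario(nx = 12, ny = 12, delta = c(bio1 = 2, bio12 = 0),
                             noise_sd = c(bio1 = 0, bio12 = 0), seed = 4)
  clim2 <- generate_landscape(scn2)
  expect_equal(clim2$period2$bio1, clim2$period1$bio1 + 2)
  expect_equal(clim2$period2$bio12, clim2$period1$bio12)
  # same seed -> bit-identical; different seed -> noise differs
  scn_n <- landscape_scenario(nx = 12, ny = 12, seed = 9)
  expect_identical(generate_landscape(scn_n), generate_landscape(scn_n))
  scn_m <- landscape_scenario(nx = 12, ny = 12, seed = 10)
  clim_n <- generate_landscape(scn_n)
  clim_m <- generate_landscape(scn_m)
  expect_false(identical(clim_n$period1$bio1, clim_m$period1$bio1))
  # the deterministic part (gradient) is unchanged between the two seeds
  expect_equal(clim_n$period1$x_km, clim_m$period1$x_km)
  expect_error(landscape_scenario(nx = 5), "at least 10")
  # every gradient variable has a delta entry, defaulting to 0
  expect_equal(sort(names(scn_n$delta)), sort(scn_n$gradient$var))
})

test_that("occupancy follows the suitability/dispersal/persistence set rules", {
  scn <- landscape_scenario(nx = 20, ny = 20, delta = c(bio1 = 1, bio12 = 0),
                            noise_sd = c(bio1 = 0, bio12 = 0), seed = 6)
  clim <- generate_landscape(scn)
  for (pars in list(list(d = Inf, p = 0, det = 1),
                    list(d = 0, p = 0, det = 1),
                    list(d = 120, p = 0.5, det = 0.8),
                    list(d = 60, p = 1, det = 0.9))) {
    sp <- species_scenario(optimum = c(bio1 = 8, bio12 = 550),
                           tolerance = c(bio1 = 1.2, bio12 = 120),
                           dispersal_limit_km = pars$d,
                           persistence_prob = pars$p,
                           detection_prob = pars$det, seed = 77)
    got <- generate_occupancy(sp, clim$period1, clim$period2)
    want <- oracle_occupancy(sp, clim$period1, clim$period2)
    expect_equal(got$period1$cell_id, want$occ1)
    expect_equal(got$period2$cell_id, want$occ2)
  }
})

test_that("a static world with full tracking keeps occupancy identical", {
  scn <- landscape_scenario(nx = 15, ny = 15, delta = c(bio1 = 0, bio12 = 0),
                            noise_sd = c(bio1 = 0, bio12 = 0), seed = 3)
  clim <- generate_landscape(scn)
  sp <- species_scenario(optimum = c(bio1 = 8, bio12 = 500),
                         tolerance = c(bio1 = 1.5, bio12 = 150), seed = 5)
  occ <- generate_occupancy(sp, clim$period1, clim$period2)
  expect_equal(occ$period1$cell_id, occ$period2$cell_id)
})

test_that("zero dispersal under a shifted climate can only contract the range", {
  scn <- landscape_scenario(nx = 20, ny = 20, delta = c(bio1 = 1.5, bio12 = 0),
                            noise_sd = c(bio1 = 0, bio12 = 0), seed = 8)
  clim <- generate_landscape(scn)
  sp <- species_scenario(optimum = c(bio1 = 8, bio12 = 550),
                         tolerance = c(bio1 = 1.2, bio12 = 200),
                         dispersal_limit_km = 0, seed = 9)
  occ <- generate_occupancy(sp, clim$period1, clim$period2)
  expect_true(all(occ$period2$cell_id %in% occ$period1$cell_id))
})

test_that("full persistence with zero dispersal retains the whole range", {
  scn <- landscape_scenario(nx = 15, ny = 15, delta = c(bio1 = 2, bio12 = 0),
                            noise_sd = c(bio1 = 0, bio12 = 0), seed = 12)
  clim <- generate_landscape(scn)
  sp <- species_scenario(optimum = c(bio1 = 8, bio12 = 500),
                         tolerance = c(bio1 = 1.5, bio12 = 150),
                         dispersal_limit_km = 0, persistence_prob = 1, seed = 13)
  occ <- generate_occupancy(sp, clim$period1, clim$period2)
  expect_true(all(occ$period1$cell_id %in% occ$period2$cell_id))
})

test_that("without persistence every current cell is currently suitable", {
  scn <- landscape_scenario(nx = 15, ny = 15, seed = 14)
  clim <- generate_landscape(scn)
  sp <- species_scenario(optimum = c(bio1 = 10, bio12 = 500),
                         tolerance = c(bio1 = 1.5, bio12 = 150),
                         persistence_prob = 0, detection_prob = 1, seed = 15)
  occ <- generate_occupancy(sp, clim$period1, clim$period2)
  clim2 <- clim$period2[match(occ$period2$cell_id, clim$period2$cell_id), ]
  suit <- exp(-0.5 * (((clim2$bio1 - 10) / 1.5)^2 + ((clim2$bio12 - 500) / 150)^2))
  expect_true(all(suit >= sp$suitability_threshold))
})

test_that("degenerate species name the empty period", {
  scn <- landscape_scenario(nx = 10, ny = 10, delta = c(bio1 = 30, bio12 = 0),
                            noise_sd = c(bio1 = 0, bio12 = 0), seed = 16)
  clim <- generate_landscape(scn)
  nowhere <- species_scenario(optimum = c(bio1 = 100, bio12 = 500),
                              tolerance = c(bio1 = 1, bio12 = 100), seed = 17)
  expect_error(generate_occupancy(nowhere, clim$period1, clim$period2),
               "period 1")
  # suitable in period 1, pushed out entirely by a huge shift, no persistence
  doomed <- species_scenario(optimum = c(bio1 = 8, bio12 = 500),
                             tolerance = c(bio1 = 1.5, bio12 = 200),
                             dispersal_limit_km = 0, persistence_prob = 0,
                             seed = 18)
  expect_error(generate_occupancy(doomed, clim$period1, clim$period2),
               "period 2")
})

test_that("trait sets are internally consistent and reproducible", {
  ts <- generate_trait_set(25, seed = 19)
  expect_setequal(ts$tree$tip.label, ts$traits$species)
  for (v in c("trophic_level", "migration", "habitat_openness")) {
    expect_true(all(ts$traits[[v]] %in% 1:3))
  }
  expect_true(ape::is.ultrametric(ts$tree, tol = 1e-6))
  expect_equal(max(diag(ts$C)), 1, tolerance = 1e-8)
  expect_identical(generate_trait_set(25, seed = 19)$y, ts$y)
  expect_false(identical(generate_trait_set(25, seed = 20)$y, ts$y))
})
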