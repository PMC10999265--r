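test_that("Schoener's D hits its bounds and the hand example", {
  z <- random_surface(1)
  expect_equal(schoener_d(z, z), 1)
  a <- matrix(0, 4, 4)
  b <- matrix(0, 4, 4)
  a[1:2, 1:2] <- 1
  b[3:4, 3:4] <- 1
  expect_equal(schoener_d(density_surface(a), density_surface(b)), 0)
  # 2-cell lattice: z1 = (1, 0), z2 = (0.5, 0.5)
  z1 <- density_surface(matrix(c(1, 0), 1, 2))
  z2 <- density_surface(matrix(c(0.5, 0.5), 1, 2))
  expect_equal(schoener_d(z1, z2), 0.5)
  expect_equal(schoener_d(z2, z1), schoener_d(z1, z2))
  expect_error(schoener_d(z1, random_surface(2)), "different lattices")
})

test_that("the U/S/E partition closes to 1 and handles the canonical cases", {
  z <- random_surface(3)
  p_id <- dynamics_partition(z, z)
  expect_equal(c(p_id$U, p_id$S, p_id$E), c(0, 1, 0))
  a <- matrix(0, 4, 4)
  b <- matrix(0, 4, 4)
  a[1:2, 1:2] <- 1
  b[3:4, 3:4] <- 1
  p_dis <- dynamics_partition(density_surface(a), density_surface(b))
  expect_equal(c(p_dis$U, p_dis$S, p_dis$E), c(0.5, 0, 0.5))
})

test_that("partition and D match cell-by-cell oracles on random surfaces", {
  for (s in 1:20) {
    z1 <- random_surface(s)
    z2 <- random_surface(s + 100)
    expect_equal(schoener_d(z1, z2), oracle_schoener(z1$z, z2$z),
                 tolerance = 1e-12)
    p <- dynamics_partition(z1, z2)
    o <- oracle_partition(z1$z, z1$mask, z2$z, z2$mask)
    expect_equal(c(p$U, p$S, p$E), unname(o), tolerance = 1e-12)
    expect_equal(p$U + p$S + p$E, 1, tolerance = 1e-12)
    # swapping the periods swaps U and E and fixes S
    q <- dynamics_partition(z2, z1)
    expect_equal(c(q$U, q$S, q$E), c(p$E, p$S, p$U), tolerance = 1e-12)
  }
})

test_that("the analogue mask is the cellwise AND of the availability footprints", {
  set.seed(31)
  pts1 <- cbind(rnorm(25, 40, 10), rnorm(25, 40, 10))
  pts2 <- cbind(rnorm(25, 60, 10), rnorm(25, 55, 10))
  bg1 <- cbind(runif(80, 0, 90), runif(80, 0, 90))
  bg2 <- cbind(runif(80, 20, 110), runif(80, 15, 105))
  lattice <- make_lattice(rbind(bg1, bg2), 40, margin = c(6, 6))
  z1 <- estimate_density(pts1, bg1, lattice = lattice)
  z2 <- estimate_density(pts2, bg2, lattice = lattice)
  m <- analogue_mask(z1, z2)
  expect_identical(m, (z1$bg_density > z1$trunc) & (z2$bg_density > z2$trunc))
  # identical availability: mask is the full footprint
  m_same <- analogue_mask(z1, z1)
  expect_identical(m_same, z1$bg_density > z1$trunc)
  # disjoint availability: no analogue climate
  far <- density_surface(matrix(1, 5, 5), gx = 1:5, gy = 1:5,
                         avail = matrix(FALSE, 5, 5))
  near <- density_surface(matrix(1, 5, 5), gx = 1:5, gy = 1:5)
  expect_error(analogue_mask(near, far), "no shared")
})

test_that("non-analogue mass splits into abandonment and pioneering", {
  z1 <- random_surface(41)
  z2 <- random_surface(42)
  # mask covering every occupied cell: A_n = P_n = 0
  full <- z1$mask | z2$mask
  p <- dynamics_partition(z1, z2, analogue = full)
  expect_equal(p$A_n, 0)
  expect_equal(p$P_n, 0)
  # mask excluding some occupied cells: the excluded mass is accounted for
  part <- matrix(TRUE, 10, 10)
  part[1:3, ] <- FALSE
  q <- dynamics_partition(z1, z2, analogue = part)
  expect_equal(q$A_n, sum(z1$z[1:3, ]))
  expect_equal(q$P_n, sum(z2$z[1:3, ]))
  expect_equal(q$U + q$S + q$E, 1, tolerance = 1e-12)
})

test_that("centroid shifts recover distance and compass bearing", {
  occ <- data.frame(x_km = c(0, 100, 50), y_km = c(0, 0, 80))
  shift_to <- function(dx, dy) {
    data.frame(x_km = occ$x_km + dx, y_km = occ$y_km + dy)
  }
  north <- centroid_shift(occ, shift_to(0, 100))
  expect_equal(north$distance_km, 100)
  expect_equal(north$bearing_deg, 0)
  east <- centroid_shift(occ, shift_to(100, 0))
  expect_equal(east$distance_km, 100)
  expect_equal(east$bearing_deg, 90)
  ne <- centroid_shift(occ, shift_to(100, 100))
  expect_equal(ne$distance_km, sqrt(2) * 100)
  expect_equal(ne$bearing_deg, 45)
  none <- centroid_shift(occ, occ)
  expect_equal(none$distance_km, 0)
  expect_true(is.na(none$bearing_deg))
})

test_that("full climate tracking keeps the niche stable", {
  a <- climate_space_dynamics(1)
  expect_gt(a$S, 0.9)
  expect_lt(a$U, 0.05)
  expect_lt(a$E, 0.05)
  expect_gt(a$D, 0.9)
})

test_that("dispersal limitation raises unfilling; persistence raises expansion", {
  seeds <- 1:8
  u_med <- sapply(c(Inf, 100, 50), function(d) {
    median(sapply(seeds, function(s) climate_space_dynamics(s, dispersal = d)$U))
  })
  expect_true(all(diff(u_med) > 0))
  e_med <- sapply(c(0, 1), function(p) {
    median(sapply(seeds, function(s) climate_space_dynamics(s, persistence = p)$E))
  })
  expect_true(all(diff(e_med) > 0))
})
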