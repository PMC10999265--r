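# Independent, definition-level oracles. These deliberately use plain loops
# and no code paths shared with the package implementation.

# --- bioclim straight from the definitions --------------------------------
oracle_bioclim <- function(tmean, tmin, tmax, prec) {
  # every candidate quarter enumerated explicitly
  qt <- numeric(12)
  qp <- numeric(12)
  for (m in 1:12) {
    months <- c(m, m %% 12 + 1, (m + 1) %% 12 + 1)
    qt[m] <- (tmean[months[1]] + tmean[months[2]] + tmean[months[3]]) / 3
    qp[m] <- prec[months[1]] + prec[months[2]] + prec[months[3]]
  }
  first_max <- function(x) which(x == max(x))[1]
  first_min <- function(x) which(x == min(x))[1]
  b1 <- sum(tmean) / 12
  b2 <- sum(tmax - tmin) / 12
  b5 <- max(tmax)
  b6 <- min(tmin)
  b7 <- b5 - b6
  b4 <- sqrt(sum((tmean - b1)^2) / 11) * 100
  pm <- sum(prec) / 12
  b15 <- sqrt(sum((prec - pm)^2) / 11) / (if (pm == 0) 1 else pm) * 100
  c(bio1 = b1, bio2 = b2, bio3 = if (b7 == 0) 0 else b2 / b7 * 100,
    bio4 = b4, bio5 = b5, bio6 = b6, bio7 = b7,
    bio8 = qt[first_max(qp)], bio9 = qt[first_min(qp)],
    bio10 = qt[first_max(qt)], bio11 = qt[first_min(qt)],
    bio12 = sum(prec), bio13 = max(prec), bio14 = min(prec), bio15 = b15,
    bio16 = qp[first_max(qp)], bio17 = qp[first_min(qp)],
    bio18 = qp[first_max(qt)], bio19 = qp[first_min(qt)])
}

random_monthly_series <- function(seed) {
  set.seed(seed)
  tmean <- runif(12, -5, 25)
  spread <- runif(12, 1, 8)
  list(tmean = tmean, tmin = tmean - spread, tmax = tmean + spread,
       prec = round(runif(12, 0, 250)))
}

# --- kernel density: per-node double sum ----------------------------------
oracle_kde <- function(pts, gx, gy, hx, hy) {
  out <- matrix(0, length(gx), length(gy))
  for (a in seq_along(gx)) {
    for (b in seq_along(gy)) {
      s <- 0
      for (i in seq_len(nrow(pts))) {
        s <- s + dnorm((gx[a] - pts[i, 1]) / hx) * dnorm((gy[b] - pts[i, 2]) / hy)
      }
      out[a, b] <- s / (nrow(pts) * hx * hy)
    }
  }
  out
}

# --- overlap and partition: cell-by-cell loops ----------------------------
oracle_schoener <- function(z1, z2) {
  s <- 0
  for (i in seq_along(z1)) s <- s + abs(z1[i] - z2[i])
  1 - s / 2
}

oracle_partition <- function(z1, m1, z2, m2) {
  U <- S1 <- S2 <- E <- 0
  for (i in seq_along(z1)) {
    if (m1[i] && !m2[i]) U <- U + z1[i]
    if (m1[i] && m2[i]) {
      S1 <- S1 + z1[i]
      S2 <- S2 + z2[i]
    }
    if (m2[i] && !m1[i]) E <- E + z2[i]
  }
  S <- (S1 + S2) / 2
  tot <- U + S + E
  c(U = U / tot, S = S / tot, E = E / tot)
}

# random normalized density surface on a small lattice, with a random
# occupied patch so that masks differ between draws
random_surface <- function(seed, n = 10) {
  set.seed(seed)
  z <- matrix(0, n, n)
  k <- sample(5:(n * n / 2), 1)
  idx <- sample(n * n, k)
  z[idx] <- runif(k)
  density_surface(z)
}

# --- occupancy set rules: independent brute force -------------------------
oracle_occupancy <- function(sp, climate1, climate2) {
  n <- nrow(climate1)
  suit <- function(clim) {
    s <- numeric(n)
    for (i in seq_len(n)) {
      q <- 0
      for (v in names(sp$optimum)) {
        q <- q + ((clim[[v]][i] - sp$optimum[[v]]) / sp$tolerance[[v]])^2
      }
      s[i] <- exp(-q / 2)
    }
    s
  }
  true1 <- suit(climate1) >= sp$suitability_threshold
  suit2 <- suit(climate2) >= sp$suitability_threshold
  # same RNG protocol as the generator: per-cell fixed-order draws
  set.seed(sp$seed)
  u_pers <- runif(n)
  u_det1 <- runif(n)
  u_det2 <- runif(n)
  reach <- logical(n)
  for (i in seq_len(n)) {
    if (is.infinite(sp$dispersal_limit_km)) {
      reach[i] <- any(true1)
    } else {
      for (j in which(true1)) {
        dij <- sqrt((climate1$x_km[i] - climate1$x_km[j])^2 +
                    (climate1$y_km[i] - climate1$y_km[j])^2)
        if (dij <= sp$dispersal_limit_km) {
          reach[i] <- TRUE
          break
        }
      }
    }
  }
  true2 <- (suit2 & reach) | (true1 & !suit2 & u_pers <= sp$persistence_prob)
  list(occ1 = which(true1 & u_det1 <= sp$detection_prob),
       occ2 = which(true2 & u_det2 <= sp$detection_prob))
}
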