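# Shift a lattice matrix by (di, dj) nodes; vacated nodes are zero-filled.
shift_matrix <- function(z, di, dj) {
  n <- nrow(z)
  m <- ncol(z)
  out <- matrix(0, n, m)
  src_i <- max(1, 1 - di):min(n, n - di)
  src_j <- max(1, 1 - dj):min(m, m - dj)
  if (length(src_i) && length(src_j)) {
    out[src_i + di, src_j + dj] <- z[src_i, src_j, drop = FALSE]
  }
  out
}

metric_value <- function(metric, z_hist, z_shift, m_shift) {
  if (metric == "overlap") {
    return(1 - 0.5 * sum(abs(z_hist$z - z_shift)))
  }
  p <- partition_masses(z_hist$z, z_hist$mask, z_shift, m_shift)
  total <- p$U + p$S + p$E
  if (total == 0) return(NA_real_)
  switch(metric,
         stability = p$S / total,
         unfilling = p$U / total,
         expansion = p$E / total,
         stopf("unknown metric '%s'", metric))
}

#' Translation null-model similarity test
#'
#' Tests whether the overlap/stability/expansion/unfilling between two
#' periods' density surfaces differs from what random placement would
#' produce. The historical surface is held fixed while the current surface is
#' translated by a uniform random lattice offset (within plus/minus the full
#' lattice extent per axis); mass translated outside the current period's
#' availability footprint is dropped and the shifted surface renormalized.
#' Draws retaining less than 5% of the mass are rejected and redrawn. Tail
#' p-values use the plus-one rule `p = (count + 1) / (n_reps + 1)`, so they
#' are never 0; the observed value is not part of the null sample.
#'
#' @param z_hist,z_curr `density_surface` objects on a common lattice.
#' @param metrics subset of `c("overlap", "stability", "expansion",
#'   "unfilling")`.
#' @param n_reps number of null replicates (>= 99; 1000 in a full analysis).
#' @param seed integer seed; results are bit-reproducible given it.
#' @param min_mass minimum retained mass fraction per draw (default 0.05).
#' @param keep_null keep the per-replicate null values (default TRUE).
#' @return data frame, one row per metric: `metric`, `observed`, `p_greater`,
#'   `p_less`, `n_reps`, `seed`; null samples in `attr(, "null")`.
#' @export
similarity_test <- function(z_hist, z_curr,
                            metrics = c("overlap", "stability",
                                        "expansion", "unfilling"),
                            n_reps = 1000, seed = 1, min_mass = 0.05,
                            keep_null = TRUE) {
  check_lattice(z_hist, z_curr)
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(n_reps >= 99)
  n <- length(z_hist$gx)
  m <- length(z_hist$gy)
  observed <- vapply(metrics, metric_value, numeric(1),
                     z_hist = z_hist, z_shift = z_curr$z, m_shift = z_curr$mask)
  null <- matrix(NA_real_, n_reps, length(metrics),
                 dimnames = list(NULL, metrics))
  footprint <- z_curr$avail
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    rejected <- 0
    repeat {
      di <- sample.int(2 * n - 1, 1) - n # uniform on -(n-1) .. (n-1)
      dj <- sample.int(2 * m - 1, 1) - m
      zs <- shift_matrix(z_curr$z, di, dj)
      zs[!footprint] <- 0
      retained <- sum(zs)
      if (retained >= min_mass) break
      rejected <- rejected + 1
      if (rejected > 1000) {
        stopf("similarity test: >1000 consecutive null draws retained < %g%% mass; background too small for the translation null",
              100 * min_mass)
      }
    }
    zs <- zs / retained
    ms <- zs > 0
    null[r, ] <- vapply(metrics, metric_value, numeric(1),
                        z_hist = z_hist, z_shift = zs, m_shift = ms)
  }
  res <- data.frame(
    metric = metrics,
    observed = unname(observed),
    p_greater = vapply(metrics, function(k) {
      (sum(null[, k] >= observed[k], na.rm = TRUE) + 1) / (n_reps + 1)
    }, numeric(1)),
    p_less = vapply(metrics, function(k) {
      (sum(null[, k] <= observed[k], na.rm = TRUE) + 1) / (n_reps + 1)
    }, numeric(1)),
    n_reps = n_reps,
    seed = seed,
    row.names = NULL
  )
  if (keep_null) attr(res, "null") <- null
  res
}

#' Interpret similarity-test results as lagging/tracking/switching labels
#'
#' At significance level `alpha`: significantly *higher* stability, *lower*
#' unfilling or *lower* expansion than the null each indicate that the
#' historical range (geographic space) or niche (climate space) is conserved
#' into the current period — "range lagging" / "niche tracking", reported
#' per metric. Significantly *lower* overlap than the null indicates "range
#' switching" / "niche switching".
#'
#' @param results data frame from [similarity_test()] covering all four
#'   metrics.
#' @param space `"geographic"` or `"climate"`.
#' @param alpha significance level (default 0.05).
#' @return character vector of labels (possibly empty).
#' @export
classify_outcome <- function(results, space = c("geographic", "climate"),
                             alpha = 0.05) {
  space <- match.arg(space)
  need <- c("overlap", "stability", "expansion", "unfilling")
  missing <- setdiff(need, results$metric)
  if (length(missing)) {
    stopf("similarity results missing metric(s): %s",
          paste(missing, collapse = ", "))
  }
  row <- function(k) results[results$metric == k, , drop = FALSE]
  prefix <- if (space == "geographic") "range" else "niche"
  conserve <- if (space == "geographic") "lagging" else "tracking"
  labels <- character(0)
  if (row("stability")$p_greater <= alpha) {
    labels <- c(labels, sprintf("%s %s(stability)", prefix, conserve))
  }
  if (row("unfilling")$p_less <= alpha) {
    labels <- c(labels, sprintf("%s %s(unfilling)", prefix, conserve))
  }
  if (row("expansion")$p_less <= alpha) {
    labels <- c(labels, sprintf("%s %s(expansion)", prefix, conserve))
  }
  if (row("overlap")$p_less <= alpha) {
    labels <- c(labels, sprintf("%s switching", prefix))
  }
  labels
}
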