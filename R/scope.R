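#' Climatic niche coverage of a regional niche by the global niche
#'
#' The proportion of the regional occurrence-density mass that falls inside
#' the global niche footprint (the global surface's occupancy mask), with
#' both surfaces built on the lattice of the global PCA climate space.
#' Species whose study region samples less than half of their global climatic
#' niche are conventionally excluded from shift analyses.
#'
#' @param z_regional,z_global `density_surface` objects on the same (global)
#'   lattice.
#' @return coverage in `[0, 1]`.
#' @export
niche_coverage <- function(z_regional, z_global) {
  check_lattice(z_regional, z_global)
  sum(z_regional$z[z_global$mask])
}

#' Shannon niche breadth of a density surface
#'
#' `H = -sum(p * log(p))` over the positive lattice densities, capturing both
#' the size of the occupied climate space and the evenness of its occupancy.
#'
#' @param z a normalized `density_surface` (or a nonnegative vector/matrix
#'   summing to 1).
#' @return Shannon entropy (natural log).
#' @export
niche_breadth <- function(z) {
  p <- if (inherits(z, "density_surface")) as.vector(z$z) else as.vector(z)
  if (abs(sum(p) - 1) > 1e-6) {
    stopf("density must be normalized to total mass 1 (got %.6f)", sum(p))
  }
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Species filtering gate for shift analyses
#'
#' Applies the pre-analysis filters: pelagic specialists out; at least
#' `min_occ` occurrences in each period; prevalence at most `max_prev` in
#' each period; non-native species out (unless a per-region native override
#' is set, for species native to the wider region but introduced locally);
#' global-niche coverage at least `min_coverage`; and species whose global
#' range does not overlap the study region at all are flagged
#' `no_range_overlap` (coverage `NA`). All failing reasons are listed, not
#' just the first.
#'
#' @param species data frame with columns `species`, `n_hist`, `n_curr`
#'   (occurrence counts per period), `prev_hist`, `prev_curr` (prevalence,
#'   fraction of cells/routes occupied), `pelagic`, `non_native` (logical),
#'   optional `native_override` (logical) and `coverage` (`NA` = no overlap
#'   of the global range with the study region).
#' @param min_occ minimum occurrences per period (default 20).
#' @param max_prev maximum prevalence per period (default 0.90).
#' @param min_coverage minimum global-niche coverage (default 0.50).
#' @return data frame `species`, `kept`, `reasons` (comma-joined; empty when
#'   kept).
#' @export
filter_species <- function(species, min_occ = 20, max_prev = 0.90,
                           min_coverage = 0.50) {
  need <- c("species", "n_hist", "n_curr", "prev_hist", "prev_curr")
  missing <- setdiff(need, names(species))
  if (length(missing)) {
    stopf("species table missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (anyNA(species[c("n_hist", "n_curr", "prev_hist", "prev_curr")])) {
    stopf("missing period data (counts/prevalence) for some species")
  }
  pelagic <- species$pelagic %||% rep(FALSE, nrow(species))
  non_native <- species$non_native %||% rep(FALSE, nrow(species))
  override <- species$native_override %||% rep(FALSE, nrow(species))
  coverage <- species$coverage %||% rep(1, nrow(species))
  reasons <- lapply(seq_len(nrow(species)), function(i) {
    r <- character(0)
    if (isTRUE(pelagic[i])) r <- c(r, "pelagic")
    if (species$n_hist[i] < min_occ || species$n_curr[i] < min_occ) {
      r <- c(r, "too_rare")
    }
    if (species$prev_hist[i] > max_prev || species$prev_curr[i] > max_prev) {
      r <- c(r, "too_widespread")
    }
    if (isTRUE(non_native[i]) && !isTRUE(override[i])) r <- c(r, "non_native")
    if (is.na(coverage[i])) {
      r <- c(r, "no_range_overlap")
    } else if (coverage[i] < min_coverage) {
      r <- c(r, "low_coverage")
    }
    r
  })
  data.frame(
    species = species$species,
    kept = lengths(reasons) == 0,
    reasons = vapply(reasons, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}
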