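#' Default pipeline configuration
#'
#' Thresholds follow the conventional values for two-period atlas analyses:
#' at least 20 occurrences per period, at most 90% prevalence, at least 50%
#' global-niche coverage, a 500 km dispersal background buffer, 1000 null
#' replicates and 99 importance permutations.
#'
#' @param ... overrides, merged shallowly per section.
#' @return nested named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    thresholds = list(min_occ = 20, max_prev = 0.90, min_coverage = 0.50,
                      buffer_km = 500, route_buffer_km = 21),
    kde = list(R = 100, bandwidth = "silverman", trunc_quantile = 0.01),
    null_model = list(n_reps = 1000, alpha = 0.05),
    traits_model = list(n_perm = 99),
    seed = 1
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

stage_try <- function(stage, species = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s'%s failed: %s", stage,
          if (is.null(species)) "" else paste0(" (species ", species, ")"),
          conditionMessage(e))
  })
}

# One species through PCA -> densities -> dynamics -> similarity, both spaces.
species_shift <- function(id, occ, clim, cfg, seed) {
  occ1 <- occ[occ$period == "historical", , drop = FALSE]
  occ2 <- occ[occ$period == "current", , drop = FALSE]
  bg <- select_background(occ1, occ2, clim$period1,
                          buffer_km = cfg$thresholds$buffer_km)
  bg2 <- clim$period2[match(bg$cell_id, clim$period2$cell_id), , drop = FALSE]
  pca <- fit_pca(rbind(bg[bio_names()], bg2[bio_names()]))
  sc_bg1 <- project_pca(pca, bg[bio_names()])
  sc_bg2 <- project_pca(pca, bg2[bio_names()])
  sc_occ1 <- sc_bg1[match(occ1$cell_id, bg$cell_id), , drop = FALSE]
  sc_occ2 <- sc_bg2[match(occ2$cell_id, bg$cell_id), , drop = FALSE]
  R <- cfg$kde$R
  tq <- cfg$kde$trunc_quantile
  geo <- shift_analysis(occ1[c("x_km", "y_km")], occ2[c("x_km", "y_km")],
                        bg[c("x_km", "y_km")], space = "geographic",
                        R = R, trunc_quantile = tq)
  cli <- shift_analysis(sc_occ1, sc_occ2, sc_bg1, sc_bg2, space = "climate",
                        R = R, trunc_quantile = tq)
  sim <- lapply(list(geographic = geo, climate = cli), function(a) {
    similarity_test(a$z1, a$z2, n_reps = cfg$null_model$n_reps,
                    seed = derive_seed(seed, "similarity", a$space, id),
                    keep_null = FALSE)
  })
  list(id = id, geo = geo, cli = cli, sim = sim, pca = pca)
}

dynamics_row <- function(id, a) {
  data.frame(
    species = id, space = a$space, D = a$D, U = a$U, S = a$S, E = a$E,
    A_n = a$A_n %||% NA_real_, P_n = a$P_n %||% NA_real_,
    centroid_shift_km = a$centroid_shift_km %||% NA_real_,
    bearing_deg = a$bearing_deg %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Run the full two-period shift pipeline
#'
#' Orchestrates filtering, the per-species PCA climate space, density
#' surfaces, dynamics metrics, similarity tests and (when a phylogeny and
#' trait table are supplied) the trait regressions, writing all result CSVs
#' plus a JSON run manifest to `out_dir`. Reruns with identical inputs and
#' seed produce byte-identical outputs.
#'
#' @param data list with elements `climate` (list `period1`, `period2` of
#'   climate grids), `occurrences` (long occurrence table), and optionally
#'   `tree` (`phylo`), `traits` (trait data frame) and `flags`
#'   (pelagic/non-native flags).
#' @param out_dir output directory (created if needed).
#' @param config configuration list from [default_config()] (or a YAML path
#'   readable by [read_config()]).
#' @return invisibly, a list with `filter`, `dynamics`, `similarity`,
#'   `trait_models`, `manifest`.
#' @export
run_pipeline <- function(data, out_dir, config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(default_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clim <- data$climate
  occ <- data$occurrences
  seed <- cfg$seed

  # -- niche coverage (optional: needs a global occurrence grid) ------------
  coverage_tab <- NULL
  if (!is.null(data$global_occurrences) && !is.null(data$global_climate)) {
    coverage_tab <- stage_try("coverage", expr = {
      cohort_niche_coverage(data$global_occurrences, data$global_climate,
                            occ[occ$period == "current", , drop = FALSE],
                            clim$period2, R = cfg$kde$R,
                            trunc_quantile = cfg$kde$trunc_quantile)
    })
    utils::write.csv(coverage_tab, file.path(out_dir, "niche_coverage.csv"),
                     row.names = FALSE)
  }

  # -- filtering ------------------------------------------------------------
  filter_rep <- stage_try("filter", expr = {
    ids <- sort(unique(occ$species))
    n_cells <- nrow(clim$period1)
    tab <- do.call(rbind, lapply(ids, function(id) {
      sub <- occ[occ$species == id, ]
      n1 <- sum(sub$period == "historical")
      n2 <- sum(sub$period == "current")
      data.frame(species = id, n_hist = n1, n_curr = n2,
                 prev_hist = n1 / n_cells, prev_curr = n2 / n_cells)
    }))
    if (!is.null(data$flags)) {
      tab <- merge(tab, data$flags, by = "species", all.x = TRUE, sort = TRUE)
    }
    if (!is.null(coverage_tab)) {
      tab <- merge(tab, coverage_tab, by = "species", all.x = TRUE, sort = TRUE)
    }
    filter_species(tab, min_occ = cfg$thresholds$min_occ,
                   max_prev = cfg$thresholds$max_prev,
                   min_coverage = cfg$thresholds$min_coverage)
  })
  utils::write.csv(filter_rep, file.path(out_dir, "filter_report.csv"),
                   row.names = FALSE)
  kept <- filter_rep$species[filter_rep$kept]

  # -- densities, dynamics, similarity --------------------------------------
  dyn_rows <- list()
  sim_rows <- list()
  for (id in kept) {
    res <- stage_try("shift-analysis", id, {
      species_shift(id, occ[occ$species == id, , drop = FALSE], clim, cfg, seed)
    })
    dyn_rows[[id]] <- rbind(dynamics_row(id, res$geo), dynamics_row(id, res$cli))
    for (space in names(res$sim)) {
      s <- res$sim[[space]]
      labels <- classify_outcome(s, space = space, alpha = cfg$null_model$alpha)
      s$species <- id
      s$space <- space
      s$label <- paste(labels, collapse = ";")
      sim_rows[[paste(id, space)]] <- s
    }
  }
  dynamics <- do.call(rbind, c(dyn_rows, list(make.row.names = FALSE)))
  similarity <- do.call(rbind, c(sim_rows, list(make.row.names = FALSE)))
  similarity <- similarity[c("species", "space", "metric", "observed",
                             "p_greater", "p_less", "n_reps", "seed", "label")]
  utils::write.csv(dynamics, file.path(out_dir, "dynamics.csv"), row.names = FALSE)
  utils::write.csv(similarity, file.path(out_dir, "similarity.csv"),
                   row.names = FALSE)

  # -- trait models ----------------------------------------------------------
  trait_models <- NULL
  if (is.null(data$tree) || is.null(data$traits)) {
    warnf("phylogeny or trait table not supplied; trait-model stage skipped")
  } else {
    trait_models <- stage_try("trait-models", expr = {
      fit_trait_models(dynamics, data$traits, data$tree,
                       n_perm = cfg$traits_model$n_perm,
                       seed = derive_seed(seed, "traits"))
    })
    utils::write.csv(trait_models$coefficients,
                     file.path(out_dir, "trait_models.csv"), row.names = FALSE)
    jsonlite::write_json(trait_models$summaries,
                         file.path(out_dir, "trait_models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "nichedyn",
    version = as.character(utils::packageVersion("nichedyn")),
    config = cfg,
    n_species_input = length(unique(occ$species)),
    n_species_kept = length(kept),
    decisions = list(
      bandwidth = "per-axis Silverman normal-reference rule (bw.nrd0)",
      truncation = sprintf("background density below its %g quantile of positive values treated as unavailable", cfg$kde$trunc_quantile),
      stability = "S* averages the two periods' shared-region masses before standardization",
      bearing = "0 deg = grid north (+y), clockwise",
      pca = "variables centred and unit-scaled; fitted on the pooled two-period background"
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(filter = filter_rep, dynamics = dynamics,
                 similarity = similarity, trait_models = trait_models,
                 manifest = manifest))
}

#' Global-vs-regional niche coverage for a species cohort
#'
#' Fits the global PCA climate space on the global grid's climate, builds
#' per-species availability-corrected density surfaces of the global and the
#' regional (current-period) occurrences on that shared lattice, and returns
#' each species' coverage: the proportion of its regional density mass inside
#' its global niche footprint. Species absent from the global grid get
#' coverage `NA` (no range overlap with the study region's source range);
#' species with fewer occurrences than the KDE floor on either side get
#' coverage 1 (undefined; such species fail the rarity filter anyway).
#'
#' @param global_occ global occurrence table (`species`, `cell_id`).
#' @param global_clim global climate grid.
#' @param regional_occ regional current-period occurrence table.
#' @param regional_clim regional current-period climate grid.
#' @param R lattice resolution.
#' @param trunc_quantile availability truncation quantile.
#' @return data frame `species`, `coverage`.
#' @export
cohort_niche_coverage <- function(global_occ, global_clim, regional_occ,
                                  regional_clim, R = 100,
                                  trunc_quantile = 0.01) {
  gpca <- fit_pca(global_clim[bio_names()])
  bg_scores <- project_pca(gpca, global_clim[bio_names()])
  h <- c(stats::bw.nrd0(bg_scores[, 1]), stats::bw.nrd0(bg_scores[, 2]))
  lattice <- make_lattice(bg_scores, R, margin = h / 2)
  ids <- sort(unique(regional_occ$species))
  cov <- vapply(ids, function(id) {
    gcells <- global_occ$cell_id[global_occ$species == id]
    if (!length(gcells)) return(NA_real_)
    rcells <- regional_occ$cell_id[regional_occ$species == id]
    if (length(gcells) < 20 || length(rcells) < 20) return(1)
    g_sc <- bg_scores[match(gcells, global_clim$cell_id), , drop = FALSE]
    r_clim <- regional_clim[match(rcells, regional_clim$cell_id), , drop = FALSE]
    r_sc <- project_pca(gpca, r_clim[bio_names()])
    zg <- estimate_density(g_sc, bg_scores, R = R, lattice = lattice,
                           trunc_quantile = trunc_quantile)
    zr <- estimate_density(r_sc, bg_scores, R = R, lattice = lattice,
                           trunc_quantile = trunc_quantile)
    niche_coverage(zr, zg)
  }, numeric(1))
  data.frame(species = ids, coverage = unname(cov), stringsAsFactors = FALSE)
}

#' Fit trait regressions for every dynamics metric
#'
#' Logit-transforms each metric (U, S, E per space), standardizes the traits,
#' and runs exhaustive AIC subset selection under PGLS, followed by
#' permutation importance of the selected predictors. Species missing from
#' the phylogeny are dropped with a message.
#'
#' @param dynamics dynamics table from [run_pipeline()] (or equivalent).
#' @param traits trait data frame (`species` + numeric traits).
#' @param tree `ape::phylo`.
#' @param n_perm importance permutations (default 99).
#' @param seed integer.
#' @return list: `coefficients` (long data frame over responses) and
#'   `summaries` (per-response lambda, R2, AIC, selected set, importance).
#' @export
fit_trait_models <- function(dynamics, traits, tree, n_perm = 99, seed = 1) {
  trait_cols <- setdiff(names(traits),
                        c("species", "pelagic", "non_native", "native_override"))
  ids <- intersect(dynamics$species, traits$species)
  dropped <- setdiff(ids, tree$tip.label)
  if (length(dropped)) {
    message("species missing from the phylogeny, dropped: ",
            paste(dropped, collapse = ", "))
    ids <- setdiff(ids, dropped)
  }
  tree <- ape::keep.tip(tree, ids)
  traits <- traits[match(ids, traits$species), , drop = FALSE]
  X <- standardize_traits(traits[c("species", trait_cols)])
  coef_rows <- list()
  summaries <- list()
  for (space in unique(dynamics$space)) {
    for (metric in c("U", "S", "E")) {
      d <- dynamics[dynamics$space == space, , drop = FALSE]
      y <- d[[metric]][match(ids, d$species)]
      if (anyNA(y)) next
      yl <- stats::setNames(logit_metric(y, length(ids)), ids)
      fit <- aic_select(yl, X, tree)
      key <- paste(space, metric, sep = "_")
      imp <- if (length(fit$selected)) {
        permutation_importance(fit, fit$selected, n_iter = n_perm,
                               seed = derive_seed(seed, "imp", key))
      } else {
        data.frame(predictor = character(0), importance = numeric(0),
                   n_iterations = integer(0), seed = integer(0))
      }
      coef_rows[[key]] <- data.frame(
        response = key,
        term = names(fit$coefficients),
        estimate = unname(fit$coefficients),
        ci_lower = unname(fit$ci[, "lower"]),
        ci_upper = unname(fit$ci[, "upper"]),
        importance = imp$importance[match(names(fit$coefficients), imp$predictor)],
        stringsAsFactors = FALSE
      )
      summaries[[key]] <- list(
        response = key, n_species = fit$n, lambda = fit$lambda,
        r2 = fit$r2, r2_obs = fit$r2_obs, AIC = fit$AIC,
        selected = as.list(fit$selected)
      )
    }
  }
  list(coefficients = do.call(rbind, c(coef_rows, list(make.row.names = FALSE))),
       summaries = summaries)
}
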