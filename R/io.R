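# File formats. One fixed CSV dialect throughout: UTF-8, comma-separated,
# header row, '.' decimal. All readers/writers are thin wrappers so the
# column contracts live in one place.

#' Read / write an occurrence table
#'
#' Columns: `species`, `period`, `cell_id`, `x_km`, `y_km`.
#' @param path file path.
#' @rdname occurrence_io
#' @export
read_occurrences <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "period", "cell_id", "x_km", "y_km")
  missing <- setdiff(need, names(x))
  if (length(missing)) stopf("occurrence file %s missing column(s): %s",
                             path, paste(missing, collapse = ", "))
  x
}

#' @param x table to write.
#' @rdname occurrence_io
#' @export
write_occurrences <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a climate grid
#'
#' Columns: `cell_id`, `x_km`, `y_km`, `bio1`..`bio19`.
#' @param path file path.
#' @rdname climate_io
#' @export
read_climate_grid <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "x_km", "y_km", bio_names())
  missing <- setdiff(need, names(x))
  if (length(missing)) stopf("climate file %s missing column(s): %s",
                             path, paste(missing, collapse = ", "))
  x
}

#' @param x table to write.
#' @rdname climate_io
#' @export
write_climate_grid <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a trait table
#'
#' Columns: `species` plus numeric trait columns (body mass, hand wing
#' index, trophic level, migration, habitat openness, range size, breeding
#' latitude, niche breadth); optional logical flag columns `pelagic`,
#' `non_native`, `native_override`.
#' @param path file path.
#' @export
read_traits <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(x)) stopf("trait file %s has no 'species' column", path)
  x
}

#' Read a Newick phylogeny
#' @param path file path.
#' @return an `ape::phylo`.
#' @export
read_phylogeny <- function(path) ape::read.tree(path)

#' Read a pipeline / scenario configuration from YAML
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Aggregate raw visit records into per-period presences
#'
#' A unit (cell or route) is present for a period iff it has at least one
#' qualifying record within the period's years; duplicates collapse to one
#' presence. Records falling outside every period are skipped (count
#' reported via `message()`).
#'
#' @param records data frame with `species`, `cell_id`, `year` and,
#'   optionally, `x_km`, `y_km` (carried through).
#' @param periods named list of integer year vectors.
#' @return data frame `species`, `period`, `cell_id` (+ coordinates),
#'   one row per presence.
#' @export
aggregate_presence <- function(records, periods) {
  stopifnot(all(c("species", "cell_id", "year") %in% names(records)))
  all_years <- unlist(periods)
  outside <- !(records$year %in% all_years)
  if (any(outside)) {
    message(sum(outside), " record(s) outside every period skipped")
    records <- records[!outside, , drop = FALSE]
  }
  coord <- intersect(c("x_km", "y_km"), names(records))
  out <- lapply(names(periods), function(p) {
    sub <- records[records$year %in% periods[[p]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    u <- unique(sub[c("species", "cell_id", coord)])
    cbind(u[, "species", drop = FALSE], period = p,
          u[, c("cell_id", coord), drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$species, out$period, out$cell_id), , drop = FALSE]
}
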