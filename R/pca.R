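#' Fit the shared climate PCA
#'
#' Fits a principal component analysis on a background climate table. The
#' variables are centred and (by default) scaled to unit standard deviation
#' before eigendecomposition, since the bioclim variables are on
#' incommensurate units (degrees C vs mm). Zero-variance variables are dropped
#' with a warning rather than an error.
#'
#' @param x data frame or matrix of climate variables (rows = cells/points).
#' @param scale. scale variables to unit sd (default TRUE).
#' @return object of class `climate_pca`: centering means, scaling sds,
#'   full rotation matrix, per-axis variance-explained fractions.
#' @export
fit_pca <- function(x, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stopf("PCA needs at least 3 rows, got %d", nrow(x))
  sds <- apply(x, 2, stats::sd)
  drop <- names(which(sds == 0))
  if (length(drop)) {
    warnf("dropping zero-variance variable(s): %s", paste(drop, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stopf("need at least 2 variables with nonzero variance")
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    center = p$center,
    scale = if (isTRUE(scale.)) p$scale else rep(1, ncol(x)),
    rotation = p$rotation,
    var_explained = ve,
    dropped = drop
  ), class = "climate_pca")
}

#' Project climate rows into a fitted PCA space
#'
#' @param model a `climate_pca` from [fit_pca()].
#' @param x data frame/matrix containing at least the model's variables.
#' @param n_axes number of axes to return (default 2).
#' @return matrix of scores, columns `PC1`, `PC2`, ...
#' @export
project_pca <- function(model, x, n_axes = 2) {
  stopifnot(inherits(model, "climate_pca"))
  vars <- rownames(model$rotation)
  x <- as.matrix(as.data.frame(x)[vars])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  scores <- xs %*% model$rotation[, seq_len(n_axes), drop = FALSE]
  colnames(scores) <- colnames(model$rotation)[seq_len(n_axes)]
  scores
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("Climate PCA:", nrow(x$rotation), "variables\n")
  cat("variance explained (axes 1-2):",
      sprintf("%.3f %.3f", x$var_explained[1], x$var_explained[2]), "\n")
  invisible(x)
}
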