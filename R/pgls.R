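#' Squeeze-then-logit transform for proportion-valued metrics
#'
#' Dynamics metrics lie in `[0, 1]` and can hit the boundaries exactly; the
#' usual remedy squeezes them towards 0.5 by the sample size before the logit:
#' `y' = (y * (n - 1) + 0.5) / n`, then `log(y' / (1 - y'))`. Strictly
#' increasing in `y` for fixed `n`, and maps 0 and 1 to finite values.
#'
#' @param y numeric in `[0, 1]`.
#' @param n sample-size context (here: number of species).
#' @return transformed values.
#' @export
logit_metric <- function(y, n) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stopf("metric values must lie in [0, 1]")
  }
  ys <- (y * (n - 1) + 0.5) / n
  log(ys / (1 - ys))
}

#' Centre and standardize a trait table
#'
#' Each numeric (or ordinal-coded) column is centred and scaled to unit
#' standard deviation (sample sd, n-1 denominator). Ordinal traits are
#' treated as numeric on their coded scale.
#'
#' @param traits data frame of numeric columns (a `species` column, if
#'   present, is carried through as rownames).
#' @return numeric matrix of standardized predictors.
#' @export
standardize_traits <- function(traits) {
  traits <- as.data.frame(traits)
  if ("species" %in% names(traits)) {
    rn <- traits$species
    traits$species <- NULL
  } else {
    rn <- rownames(traits)
  }
  X <- as.matrix(traits)
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("constant trait column(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  }
  X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  rownames(X) <- rn
  X
}

# Build the whitening transform for V(lambda) = lambda*C + (1-lambda)*diag(C).
# When the tree is ultrametric (diag(C) constant) V shares C's eigenbasis for
# every lambda, so one eigendecomposition serves the whole profile search;
# otherwise each lambda needs its own Cholesky factor.
pgls_transform <- function(C) {
  dC <- diag(C)
  if (max(dC) - min(dC) < 1e-8 * mean(dC)) {
    e <- eigen(C, symmetric = TRUE)
    list(type = "eigen", U = e$vectors, eval = e$values, c0 = mean(dC), C = C)
  } else {
    list(type = "chol", C = C, dC = dC)
  }
}

# Profile GLS at fixed lambda: returns beta, ML sigma2, logLik, XtVinvX.
pgls_profile <- function(y, Xd, trans, lambda) {
  n <- length(y)
  if (trans$type == "eigen") {
    d <- lambda * trans$eval + (1 - lambda) * trans$c0
    w <- 1 / sqrt(d)
    yt <- crossprod(trans$U, y) * w
    Xt <- crossprod(trans$U, Xd) * w
    logdet <- sum(log(d))
  } else {
    V <- lambda * trans$C + (1 - lambda) * diag(trans$dC)
    L <- chol(V)
    yt <- backsolve(L, y, transpose = TRUE)
    Xt <- backsolve(L, Xd, transpose = TRUE)
    logdet <- 2 * sum(log(diag(L)))
  }
  XtX <- crossprod(Xt)
  beta <- tryCatch(solve(XtX, crossprod(Xt, yt)),
                   error = function(e) stopf("singular X'V^-1X: %s", conditionMessage(e)))
  r <- yt - Xt %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(beta = drop(beta), sigma2 = sigma2, logLik = ll, rss = rss,
       XtX = XtX, yt = yt, Xt = Xt)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + eps` with `cov(eps) = sigma2 * (lambda * C +
#' (1 - lambda) * diag(C))`, `C` the tree's shared-path-length matrix.
#' For fixed lambda the GLS estimates and profile-ML sigma2 are closed form;
#' lambda is estimated by maximizing the profile log-likelihood over the
#' closed interval `[0, 1]` (bounded 1-D optimization, tolerance 1e-8, with
#' both endpoints checked). lambda = 0 reduces to ordinary least squares;
#' lambda = 1 is Brownian motion.
#'
#' @param y named response vector (names = tree tip labels).
#' @param X predictor matrix (no intercept column; one is added), rownames =
#'   tip labels. `NULL` fits the intercept-only model.
#' @param tree an `ape::phylo` tree, or a precomputed transform from the
#'   internal eigen/Cholesky factorization (used by [aic_select()]).
#' @param lambda fix lambda at this value instead of estimating it.
#' @return object of class `pgls_fit`: coefficients with 95% confidence
#'   intervals, `sigma2`, `lambda`, `logLik`, `AIC` (k counts coefficients +
#'   sigma2 + lambda), whitened-space `r2` and observation-space `r2_obs`.
#' @export
pgls_fit <- function(y, X = NULL, tree, lambda = NULL) {
  if (inherits(tree, "phylo")) {
    if (!ape::is.ultrametric(tree, tol = 1e-6)) {
      warnf("tree is not ultrametric; proceeding with its raw covariance")
    }
    C <- ape::vcv(tree)
    ord <- rownames(C)
    if (!is.null(names(y))) {
      if (!setequal(names(y), ord)) stopf("response names do not match tree tips")
      y <- y[ord]
      if (!is.null(X)) X <- X[ord, , drop = FALSE]
    }
    trans <- pgls_transform(C)
  } else {
    trans <- tree
  }
  y <- as.numeric(y)
  n <- length(y)
  Xd <- cbind(`(Intercept)` = rep(1, n), X)
  k_coef <- ncol(Xd)
  estimate_lambda <- is.null(lambda)
  if (estimate_lambda && n <= k_coef + 2) {
    stopf("need n > k + 2 to estimate lambda (n = %d, k = %d)", n, k_coef)
  }
  if (estimate_lambda) {
    obj <- function(l) pgls_profile(y, Xd, trans, l)$logLik
    opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, obj(0), obj(1))
    lambda <- cand[which.max(ll)]
  }
  fit <- pgls_profile(y, Xd, trans, lambda)
  # intercept-only fit at the same lambda gives the whitened-space TSS
  null_fit <- pgls_profile(y, Xd[, 1, drop = FALSE], trans, lambda)
  r2 <- 1 - fit$rss / null_fit$rss
  yhat <- drop(Xd %*% fit$beta)
  r2_obs <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  vcov_beta <- fit$sigma2 * solve(fit$XtX)
  se <- sqrt(diag(vcov_beta))
  zq <- stats::qnorm(0.975)
  k <- k_coef + 2 # coefficients + sigma2 + lambda
  structure(list(
    coefficients = fit$beta,
    se = se,
    ci = cbind(lower = fit$beta - zq * se, upper = fit$beta + zq * se),
    sigma2 = fit$sigma2,
    lambda = lambda,
    lambda_estimated = estimate_lambda,
    logLik = fit$logLik,
    AIC = 2 * k - 2 * fit$logLik,
    k = k,
    r2 = r2,
    r2_obs = r2_obs,
    tss_whitened = null_fit$rss,
    n = n,
    y = y,
    X = X,
    trans = trans
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: n = %d, lambda = %.4f%s, R2 = %.3f, AIC = %.2f\n",
              x$n, x$lambda, if (x$lambda_estimated) " (ML)" else " (fixed)",
              x$r2, x$AIC))
  tab <- cbind(estimate = x$coefficients, x$ci)
  print(round(tab, 4))
  invisible(x)
}

#' Exhaustive AIC-based predictor-subset selection for PGLS
#'
#' Fits every subset of the candidate predictors (intercept always included)
#' and returns the minimum-AIC fit. Ties (delta AIC < 1e-6) are broken toward
#' fewer predictors, then lexicographically by predictor names. Subsets that
#' fail to fit are skipped with a warning.
#'
#' @param y named response vector.
#' @param X candidate predictor matrix (<= 12 columns).
#' @param tree `ape::phylo`.
#' @return the selected `pgls_fit`, with `$selected` (predictor names) and
#'   `$selection_table` (subset, AIC) attached.
#' @export
aic_select <- function(y, X, tree) {
  p <- ncol(X)
  if (p > 12) stopf("at most 12 candidate predictors (got %d); exhaustive search only", p)
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warnf("tree is not ultrametric; proceeding with its raw covariance")
  }
  C <- ape::vcv(tree)
  ord <- rownames(C)
  if (!is.null(names(y))) {
    y <- y[ord]
    X <- X[ord, , drop = FALSE]
  }
  trans <- pgls_transform(C)
  subsets <- lapply(0:(2^p - 1), function(mask) which(bitwAnd(mask, 2^(0:(p - 1))) > 0))
  # order by size then lexicographically by member names, so the first
  # minimum encountered is the tie-break winner
  keynames <- vapply(subsets, function(s) paste(colnames(X)[s], collapse = "|"),
                     character(1))
  ordidx <- order(lengths(subsets), keynames)
  subsets <- subsets[ordidx]
  fits <- vector("list", length(subsets))
  aics <- rep(Inf, length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    Xi <- if (length(s)) X[, s, drop = FALSE] else NULL
    fits[i] <- list(tryCatch(pgls_fit(y, Xi, trans),
                             error = function(e) {
                               warnf("subset {%s} failed to fit: %s",
                                     paste(colnames(X)[s], collapse = ","),
                                     conditionMessage(e))
                               NULL
                             }))
    if (!is.null(fits[[i]])) aics[i] <- fits[[i]]$AIC
  }
  best <- which(aics <= min(aics) + 1e-6)[1]
  fit <- fits[[best]]
  fit$selected <- colnames(X)[subsets[[best]]]
  fit$selection_table <- data.frame(
    subset = vapply(subsets, function(s) paste(colnames(X)[s], collapse = "+"),
                    character(1)),
    n_predictors = lengths(subsets),
    AIC = aics
  )
  fit
}

#' Permutation variable importance for a PGLS fit
#'
#' For each selected predictor, permutes its column across species and
#' recomputes the whitened-space explained variance using the original fitted
#' coefficients and lambda (no refit); importance is the mean drop in
#' explained variance over `n_iter` permutations.
#'
#' @param fit a `pgls_fit` with predictors.
#' @param predictors which predictors to assess (default: all in the fit).
#' @param n_iter number of permutations (default 99).
#' @param seed integer seed.
#' @return data frame `predictor`, `importance`, `n_iterations`, `seed`.
#' @export
permutation_importance <- function(fit, predictors = colnames(fit$X),
                                   n_iter = 99, seed = 1) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (is.null(fit$X)) stopf("fit has no predictors to permute")
  missing <- setdiff(predictors, colnames(fit$X))
  if (length(missing)) {
    stopf("predictor(s) not in fit: %s", paste(missing, collapse = ", "))
  }
  n <- fit$n
  Xd <- cbind(`(Intercept)` = rep(1, n), fit$X)
  whiten <- function(M) {
    if (fit$trans$type == "eigen") {
      d <- fit$lambda * fit$trans$eval + (1 - fit$lambda) * fit$trans$c0
      crossprod(fit$trans$U, M) / sqrt(d)
    } else {
      V <- fit$lambda * fit$trans$C + (1 - fit$lambda) * diag(fit$trans$dC)
      backsolve(chol(V), M, transpose = TRUE)
    }
  }
  yt <- drop(whiten(matrix(fit$y, ncol = 1)))
  r2_of <- function(Xperm) {
    rt <- yt - drop(whiten(Xperm) %*% fit$coefficients)
    1 - sum(rt^2) / fit$tss_whitened
  }
  r2_orig <- r2_of(Xd)
  set.seed(seed)
  imp <- vapply(predictors, function(p) {
    drops <- vapply(seq_len(n_iter), function(i) {
      Xp <- Xd
      Xp[, p] <- Xp[sample.int(n), p]
      r2_orig - r2_of(Xp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  data.frame(predictor = predictors, importance = unname(imp),
             n_iterations = n_iter, seed = seed, row.names = NULL)
}
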