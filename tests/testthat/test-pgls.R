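test_that("the squeeze-logit transform behaves at its anchors", {
  expect_equal(logit_metric(0.5, 100), 0)
  expect_equal(logit_metric(1, 100), log(0.995 / 0.005), tolerance = 1e-12)
  expect_equal(round(logit_metric(1, 100), 3), 5.293)
  y <- seq(0, 1, by = 0.05)
  expect_true(all(diff(logit_metric(y, 50)) > 0))
  expect_true(all(is.finite(logit_metric(c(0, 1), 10))))
  expect_error(logit_metric(1.2, 10), "\\[0, 1\\]")
})

test_that("trait standardization centres and unit-scales with the n-1 sd", {
  out <- standardize_traits(data.frame(a = c(1, 2, 3)))
  expect_equal(as.vector(out), c(-1, 0, 1))
  again <- standardize_traits(as.data.frame(out))
  expect_equal(unname(again), unname(out), tolerance = 1e-12)
  two <- standardize_traits(data.frame(a = c(4, 9, 1, 5), b = c(4, 9, 1, 5)))
  expect_equal(two[, 1], two[, 2])
  expect_error(standardize_traits(data.frame(a = 1:3, flat = rep(2, 3))), "flat")
})

test_that("PGLS at lambda 0 and on a star tree reduces to OLS", {
  ts <- generate_trait_set(60, beta_true = c(body_mass = 0.6), lambda_true = 0.5,
                           seed = 81)
  X <- ts$X[, c("body_mass", "range_size")]
  ols <- lm(ts$y ~ X)
  f0 <- pgls_fit(ts$y, X, ts$tree, lambda = 0)
  expect_lt(max(abs(f0$coefficients - coef(ols))), 1e-8)
  star <- ape::read.tree(text = paste0("(",
    paste(ts$tree$tip.label, ":1", collapse = ","), ");"))
  fs <- pgls_fit(ts$y, X, star)
  expect_lt(max(abs(fs$coefficients - coef(ols))), 1e-8)
})

test_that("lambda 1 on a two-tip tree matches the hand-computed GLS", {
  tree <- ape::read.tree(text = "(a:1,b:1);")
  y <- c(a = 1.3, b = 2.9)
  # V = C = I for two tips at depth 1, so GLS = OLS: intercept = mean(y)
  fit <- pgls_fit(y, NULL, tree, lambda = 1)
  expect_equal(unname(fit$coefficients), mean(y), tolerance = 1e-10)
  expect_equal(fit$sigma2, sum((y - mean(y))^2) / 2, tolerance = 1e-10)
  # hand-built unbalanced covariance via an explicit non-ultrametric tree
  tree2 <- ape::read.tree(text = "(a:2,b:1);")
  y2 <- c(a = 3, b = 1)
  suppressWarnings(fit2 <- pgls_fit(y2, NULL, tree2, lambda = 1))
  # closed form: beta = (1'V^-1 1)^-1 1'V^-1 y with V = diag(2, 1)
  expect_equal(unname(fit2$coefficients),
               (3 / 2 + 1) / (1 / 2 + 1), tolerance = 1e-10)
})

test_that("profile likelihood is maximized on the closed interval", {
  for (s in 1:5) {
    ts <- generate_trait_set(50, beta_true = c(niche_breadth = 0.5),
                             lambda_true = runif(1), seed = 90 + s)
    X <- ts$X[, "niche_breadth", drop = FALSE]
    fit <- pgls_fit(ts$y, X, ts$tree)
    expect_gte(fit$logLik, pgls_fit(ts$y, X, ts$tree, lambda = 0)$logLik - 1e-8)
    expect_gte(fit$logLik, pgls_fit(ts$y, X, ts$tree, lambda = 1)$logLik - 1e-8)
    expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  }
})

test_that("PGLS agrees with the independent GLS implementation", {
  skip_if_not_installed("nlme")
  ts <- generate_trait_set(120, beta_true = c(hand_wing_index = 0.8,
                                              body_mass = -0.5),
                           lambda_true = 0.7, seed = 5)
  X <- ts$X[, c("hand_wing_index", "body_mass")]
  fit <- pgls_fit(ts$y, X, ts$tree)
  dat <- data.frame(y = ts$y, X, species = ts$tree$tip.label)
  ref <- nlme::gls(y ~ hand_wing_index + body_mass, data = dat,
                   correlation = ape::corPagel(0.5, ts$tree, form = ~species),
                   method = "ML")
  expect_equal(fit$lambda,
               unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("AIC is consistent with the returned likelihood and parameter count", {
  ts <- generate_trait_set(40, beta_true = c(body_mass = 1), seed = 111)
  fit <- pgls_fit(ts$y, ts$X[, c("body_mass", "migration")], ts$tree)
  k <- length(fit$coefficients) + 2
  expect_equal(fit$AIC, 2 * k - 2 * fit$logLik, tolerance = 1e-12)
})

test_that("exhaustive selection enumerates subsets and respects tie-breaks", {
  ts <- generate_trait_set(60, beta_true = c(range_size = 1.5), seed = 121)
  X1 <- ts$X[, "range_size", drop = FALSE]
  sel <- aic_select(ts$y, X1, ts$tree)
  expect_equal(nrow(sel$selection_table), 2)
  expect_setequal(sel$selection_table$subset, c("", "range_size"))
  both <- list(pgls_fit(ts$y, NULL, ts$tree), pgls_fit(ts$y, X1, ts$tree))
  expect_equal(sel$AIC, min(both[[1]]$AIC, both[[2]]$AIC))
  expect_error(aic_select(ts$y, matrix(rnorm(60 * 13), 60), ts$tree), "12")
})

test_that("trait simulation has the promised second-order structure", {
  # beta 0, sigma 1: pooled variance of y approximates the mean diagonal of C
  vals <- unlist(lapply(1:300, function(s) {
    generate_trait_set(15, beta_true = c(body_mass = 0), lambda_true = 0.6,
                       residual_sd = 1, seed = 3000 + s)$y
  }))
  expect_equal(mean(vals^2), 1, tolerance = 0.08) # diag(C) = 1 after scaling
  # lambda 0: residuals uncorrelated even across sister tips
  eps <- sapply(1:200, function(s) {
    generate_trait_set(10, beta_true = c(body_mass = 0), lambda_true = 0,
                       residual_sd = 1, seed = 5000 + s)$y
  })
  cors <- cor(t(eps))
  offdiag <- cors[upper.tri(cors)]
  expect_lt(max(abs(offdiag)), 0.35) # n = 200 draws; null sd ~ 0.07
  expect_error(generate_trait_set(10, lambda_true = 1.4), "lambda")
  expect_error(generate_trait_set(3), "at least 5")
})

test_that("permutation importance isolates the predictors that matter", {
  ts <- generate_trait_set(200, beta_true = c(hand_wing_index = 1),
                           lambda_true = 0.5, seed = 131)
  fit <- pgls_fit(ts$y, ts$X[, c("hand_wing_index", "body_mass")], ts$tree)
  imp <- permutation_importance(fit, n_iter = 99, seed = 1)
  expect_lt(abs(imp$importance[imp$predictor == "body_mass"]), 0.01)
  expect_gt(imp$importance[imp$predictor == "hand_wing_index"], 0.1)
  # a sole predictor that wholly determines y: importance ~ R2 ~ 1
  x <- ts$X[, "range_size", drop = FALSE]
  y_det <- drop(x) * 2
  names(y_det) <- ts$tree$tip.label
  fdet <- pgls_fit(y_det, x, ts$tree, lambda = 0)
  idet <- permutation_importance(fdet, n_iter = 99, seed = 2)
  expect_equal(fdet$r2, 1, tolerance = 1e-9)
  expect_gt(idet$importance, 0.9)
  expect_error(permutation_importance(fit, "niche_breadth"), "not in fit")
  # reproducible given the seed
  expect_identical(permutation_importance(fit, n_iter = 20, seed = 9),
                   permutation_importance(fit, n_iter = 20, seed = 9))
})
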