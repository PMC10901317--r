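# Synthetic-data generators

test_that("grid lattices have the combinatorially expected edge counts", {
  g <- make_grid_lattice(2, 2, "rook")
  expect_equal(length(g$geometries), 4)
  expect_equal(connectivity_report(g$weights)$edges, 4)
  g15 <- make_grid_lattice(15, 15, "rook")
  expect_equal(connectivity_report(g15$weights)$edges, 2 * 15 * 14)
  q <- make_grid_lattice(4, 5, "queen")$weights
  r <- make_grid_lattice(4, 5, "rook")$weights
  expect_true(all(r$w <= q$w))
  expect_error(make_grid_lattice(1, 5), "at least 2")
})

test_that("covariate simulation is seeded and spatially smoothed", {
  w <- row_standardize(make_grid_lattice(15, 15, "rook")$weights)
  X1 <- simulate_covariates(w, 3, phi = 0.7, seed = 10)
  X2 <- simulate_covariates(w, 3, phi = 0.7, seed = 10)
  expect_identical(X1, X2)
  # smoothed column shows significant positive autocorrelation
  m <- global_moran(X1[, 1], w, nperm = 999, seed = 1)
  expect_lt(m$p_pseudo, 0.01)
  expect_gt(m$I, 0)
  # unsmoothed columns do not (analytic p clear of significance)
  X0 <- simulate_covariates(w, 1, phi = 0, seed = 11)
  m0 <- global_moran(X0[, 1], w, inference = "randomization")
  expect_gt(m0$p_analytic, 0.05)
  expect_error(simulate_covariates(w, 2, phi = 1, seed = 1), "admissible")
})

test_that("response simulation collapses to known special cases", {
  w <- row_standardize(make_grid_lattice(4, 4, "rook")$weights)
  set.seed(3)
  X <- matrix(rnorm(16), ncol = 1, dimnames = list(NULL, "x1"))
  beta <- c(1, 2)
  # no spatial terms: y = X beta + eps with the seeded normal draw
  y <- simulate_response("OLS", w, X, list(beta = beta, sigma = 1), seed = 5)
  set.seed(5)
  eps <- rnorm(16)
  expect_equal(y, as.numeric(cbind(1, X) %*% beta) + eps, tolerance = 1e-12)
  # noiseless SAR equals the dense reduced-form solve
  y0 <- simulate_response("SAR", w, X,
                          list(beta = beta, rho = 0.5, sigma = 0), seed = 1)
  oracle <- solve(diag(16) - 0.5 * w$w, as.numeric(cbind(1, X) %*% beta))
  expect_equal(y0, as.numeric(oracle), tolerance = 1e-10)
  # determinism
  y1 <- simulate_response("SAC", w, X,
                          list(beta = beta, rho = 0.4, lambda = 0.3,
                               sigma = 1), seed = 7)
  y2 <- simulate_response("SAC", w, X,
                          list(beta = beta, rho = 0.4, lambda = 0.3,
                               sigma = 1), seed = 7)
  expect_identical(y1, y2)
  expect_error(simulate_response("SAR", w, X,
                                 list(beta = beta, rho = 1.2, sigma = 1), 1),
               "inadmissible")
})

test_that("SEM-generated data leave autocorrelated regression residuals", {
  w <- row_standardize(make_grid_lattice(10, 10, "rook")$weights)
  set.seed(19)
  X <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "x1"))
  y <- simulate_response("SEM", w, X,
                         list(beta = c(0, 1), lambda = 0.7, sigma = 1),
                         seed = 23)
  res <- lm.fit(cbind(1, X), y)$residuals
  m <- global_moran(res, w, nperm = 999, seed = 2)
  expect_lt(m$p_pseudo, 0.01)
  expect_gt(m$I, 0)
})

test_that("child survey reproduces closed-form prevalence and shifts", {
  ids <- sprintf("Z%d", 1:10)
  # zero shifts + identity correlation: P(failure) = 1 - pnorm(2)^3
  shifts <- setNames(rep(0, 10), ids)
  kids <- simulate_child_survey(shifts, 2000, zscore_corr = diag(3), seed = 1)
  cls <- classify_children(kids)
  prev <- mean(cls$ciaf_flag)
  p0 <- 1 - pnorm(2)^3
  se <- sqrt(p0 * (1 - p0) / nrow(cls))
  expect_lt(abs(prev - p0), 3 * se)
  # a -2 SD shift pushes prevalence past one half
  kids2 <- simulate_child_survey(setNames(-2, "Z1"), 500, seed = 2)
  cls2 <- classify_children(kids2)
  expect_gt(mean(cls2$ciaf_flag), 0.5)
  # determinism and validation
  expect_identical(simulate_child_survey(shifts, 50, seed = 3),
                   simulate_child_survey(shifts, 50, seed = 3))
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(simulate_child_survey(shifts, 10, zscore_corr = bad, seed = 1),
               "positive definite")
})

test_that("the bundled synthetic study is reproducible and spatially
           structured", {
  s1 <- suppressWarnings(simulate_ciaf_study(seed = 2, rows = 6, cols = 6,
                                             children_per_zone = 100))
  s2 <- suppressWarnings(simulate_ciaf_study(seed = 2, rows = 6, cols = 6,
                                             children_per_zone = 100))
  expect_identical(s1$zone_table, s2$zone_table)
  expect_equal(nrow(s1$zone_table), 36)
  expect_equal(sum(s1$zone_table$n), 3600)
  # at the default 72-zone scale the risk surface is spatially clustered
  s72 <- suppressWarnings(simulate_ciaf_study(seed = 2))
  m <- global_moran(log(s72$zone_table$rr), s72$weights, nperm = 499, seed = 4)
  expect_lt(m$p_pseudo, 0.05)
  expect_gt(m$I, 0)
})

test_that("spatial-coefficient RMSE shrinks as the lattice grows", {
  w10 <- row_standardize(make_grid_lattice(10, 10, "rook")$weights)
  w20 <- row_standardize(make_grid_lattice(20, 20, "rook")$weights)
  pars <- list(beta = c(1, 2), rho = 0.5, sigma = 1)
  r100 <- recovery_experiment("SAR", w10, pars, nreps = 100, seed = 71)
  r400 <- recovery_experiment("SAR", w20, pars, nreps = 100, seed = 72)
  expect_lt(r400$rmse[r400$parameter == "rho"],
            r100$rmse[r100$parameter == "rho"])
})

test_that("parameter recovery is unbiased for a short null experiment", {
  w <- row_standardize(make_grid_lattice(7, 7, "rook")$weights)
  out <- recovery_experiment("SAR", w,
                             list(beta = c(1, 2), rho = 0.4, sigma = 1),
                             nreps = 50, seed = 99)
  expect_true(all(c("bias", "rmse", "coverage") %in% names(out)))
  expect_lt(abs(out$bias[out$parameter == "rho"]), 0.1)
  expect_gt(out$coverage[out$parameter == "(Intercept)"], 0.8)
})
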