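# Maximum-likelihood estimation of the spatial model family

make_test_data <- function(n_side = 8, family = "SAR", rho = 0.4,
                           lambda = 0, sigma = 1, seed = 2) {
  lat <- make_grid_lattice(n_side, n_side, "rook")
  w <- row_standardize(lat$weights)
  set.seed(seed)
  X <- matrix(rnorm(n_side^2 * 2), ncol = 2,
              dimnames = list(NULL, c("x1", "x2")))
  y <- simulate_response(family, w, X,
                         list(beta = c(1, 2, -1), rho = rho, lambda = lambda,
                              sigma = sigma),
                         seed = seed + 1)
  list(y = y, X = X, w = w)
}

test_that("log-determinant term matches closed forms and the dense oracle", {
  pair <- row_standardize(from_edge_list(rbind(c("a", "b")), c("a", "b")))
  expect_equal(log_det_term(0, pair), 0)
  expect_equal(log_det_term(0.5, pair), log(1 - 0.25), tolerance = 1e-12)
  set.seed(17)
  w <- row_standardize(random_connected_weights(8))
  iv <- coef_interval(w)
  for (cf in seq(iv[1] + 0.01, iv[2] - 0.01, length.out = 9)) {
    dense <- as.numeric(determinant(diag(8) - cf * w$w)$modulus)
    expect_equal(log_det_term(cf, w), dense, tolerance = 1e-10)
  }
  expect_error(log_det_term(1, w), "log-determinant undefined")
  expect_error(log_det_term(iv[1] - 1, w), "log-determinant undefined")
})

test_that("negative_loglik agrees with closed forms and a dense oracle", {
  d <- make_test_data(5, family = "OLS", rho = 0)
  n <- length(d$y)
  ols <- fit_spatial("OLS", d$y, d$X, d$w)
  # closed-form Gaussian log-likelihood at the OLS optimum
  expect_equal(ols$loglik, -(n / 2) * (log(2 * pi * ols$sigma2) + 1),
               tolerance = 1e-10)
  par_ols <- c(ols$gamma, ols$sigma2)
  expect_equal(-negative_loglik("OLS", par_ols, d$y, d$X, d$w), ols$loglik,
               tolerance = 1e-10)
  # SAR at rho = 0 collapses to OLS at the same (beta, sigma2)
  par_sar <- c(ols$gamma, 0, ols$sigma2)
  expect_equal(negative_loglik("SAR", par_sar, d$y, d$X, d$w),
               negative_loglik("OLS", par_ols, d$y, d$X, d$w),
               tolerance = 1e-12)
  # random interior GNS point vs explicit dense evaluation
  ids <- sprintf("z%d", 1:6)
  w6 <- row_standardize(path_weights(ids))
  set.seed(9)
  X6 <- matrix(rnorm(6), ncol = 1, dimnames = list(NULL, "x1"))
  y6 <- rnorm(6)
  Xa <- cbind(1, X6, w6$w %*% X6)
  gamma <- c(0.3, -0.7, 0.2)
  val <- negative_loglik("GNS", c(gamma, 0.35, -0.25, 0.8), y6, X6, w6)
  expect_equal(-val, loglik_dense(y6, Xa, w6$w, gamma, 0.35, -0.25, 0.8),
               tolerance = 1e-10)
  expect_error(negative_loglik("SAR", c(0, 0, 0, 1.5, 1), d$y, d$X, d$w),
               "log-determinant undefined")
})

test_that("concentrated SAR estimation matches an exhaustive grid search", {
  t6 <- toy6()
  X <- matrix(t6$x1, ncol = 1, dimnames = list(NULL, "x1"))
  fit <- fit_spatial("SAR", t6$y, X, t6$w)
  # independent oracle: dense determinant + base lm.fit over a rho grid
  W <- t6$w$w
  Wy <- as.numeric(W %*% t6$y)
  Xa <- cbind(1, t6$x1)
  grid <- seq(-0.999, 0.999, by = 1e-4)
  ll <- vapply(grid, function(r) {
    yr <- t6$y - r * Wy
    f <- lm.fit(Xa, yr)
    s2 <- sum(f$residuals^2) / 6
    -(6 / 2) * (log(2 * pi * s2) + 1) +
      as.numeric(determinant(diag(6) - r * W)$modulus)
  }, numeric(1))
  expect_equal(fit$rho, grid[which.max(ll)], tolerance = 2e-4)
  expect_gte(fit$loglik + 1e-10, max(ll))
})

test_that("profile optimum reproduces the full likelihood at the packed
           parameters", {
  d <- make_test_data(7)
  for (fam in c("SAR", "SEM", "SDM", "SAC")) {
    fit <- fit_spatial(fam, d$y, d$X, d$w)
    par <- c(fit$gamma,
             if (!is.null(fit$rho)) fit$rho,
             if (!is.null(fit$lambda)) fit$lambda,
             fit$sigma2)
    expect_equal(-negative_loglik(fam, par, d$y, d$X, d$w), fit$loglik,
                 tolerance = 1e-8)
  }
})

test_that("likelihood nesting chains hold on a fixed dataset", {
  d <- make_test_data(8, family = "SAC", rho = 0.3, lambda = 0.3)
  ll <- vapply(all_families, function(fam)
    fit_spatial(fam, d$y, d$X, d$w)$loglik, numeric(1))
  tol <- 1e-6
  expect_lte(ll["OLS"], ll["SAR"] + tol)
  expect_lte(ll["SAR"], ll["SDM"] + tol)
  expect_lte(ll["SDM"], ll["GNS"] + tol)
  expect_lte(ll["OLS"], ll["SEM"] + tol)
  expect_lte(ll["SEM"], ll["SDEM"] + tol)
  expect_lte(ll["SDEM"], ll["GNS"] + tol)
  expect_lte(ll["SAR"], ll["SAC"] + tol)
  expect_lte(ll["SAC"], ll["GNS"] + tol)
  expect_lte(ll["OLS"], ll["SLX"] + tol)
  expect_lte(ll["SLX"], ll["SDM"] + tol)
})

test_that("estimates are invariant to a simultaneous permutation of zones", {
  d <- make_test_data(6)
  set.seed(44)
  perm <- sample(36)
  wp <- spatial_weights(d$w$w[perm, perm], d$w$ids[perm],
                        style = "row-standardized")
  f1 <- fit_spatial("SAC", d$y, d$X, d$w)
  f2 <- fit_spatial("SAC", d$y[perm], d$X[perm, ], wp)
  expect_lt(abs(f2$rho - f1$rho), 1e-8)
  expect_lt(abs(f2$lambda - f1$lambda), 1e-8)
  expect_lt(max(abs(f2$gamma - f1$gamma)), 1e-8)
})

test_that("residual decomposition satisfies the fitted model identity", {
  d <- make_test_data(7, family = "SAC", rho = 0.3, lambda = 0.3)
  fit <- fit_spatial("SAC", d$y, d$X, d$w)
  Ay <- d$y - fit$rho * as.numeric(d$w$w %*% d$y)
  u <- Ay - as.numeric(fit$design %*% fit$gamma)
  expect_equal(fit$u_hat, u, tolerance = 1e-8)
  expect_equal(fit$eps_hat, u - fit$lambda * as.numeric(d$w$w %*% u),
               tolerance = 1e-8)
  # spatial coefficients stay strictly inside the admissible interval
  expect_gt(fit$rho, fit$rho_interval[1])
  expect_lt(fit$rho, fit$rho_interval[2])
})

test_that("rank-deficient designs are rejected with the offending column", {
  d <- make_test_data(5)
  X <- cbind(d$X, x3 = d$X[, "x1"])
  expect_error(fit_spatial("OLS", d$y, X, d$w), "collinear")
})

test_that("numerical standard errors match the OLS closed form", {
  d <- make_test_data(7, family = "OLS", rho = 0)
  fit <- standard_errors(fit_spatial("OLS", d$y, d$X, d$w), d$w)
  Xa <- fit$design
  closed <- sqrt(diag(fit$sigma2 * solve(crossprod(Xa))))
  got <- fit$se[seq_along(closed)]
  expect_equal(unname(got), unname(closed), tolerance = 1e-4)
})

test_that("stars and information criteria follow their defining formulas", {
  expect_identical(significance_stars(c(0.04, 0.005, 0.0005, 0.2)),
                   c("*", "**", "***", ""))
  fit <- list(loglik = -10, k = 3)
  fit <- information_criteria(fit, n = 72)
  expect_equal(fit$aic, 26)
  expect_equal(fit$bic, 3 * log(72) + 20, tolerance = 1e-9)
})

test_that("SAR on spatially independent data attributes no spatial effect", {
  d <- make_test_data(8, family = "OLS", rho = 0, seed = 12)
  sar <- standard_errors(fit_spatial("SAR", d$y, d$X, d$w), d$w)
  ols <- fit_spatial("OLS", d$y, d$X, d$w)
  ci <- sar$rho + c(-1, 1) * qnorm(0.975) * sar$se[["rho"]]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
  expect_gte(sar$loglik, ols$loglik - 1e-8)
  expect_lte(sar$loglik, ols$loglik + 2)
})

test_that("fit_model builds the response from the zone table transform", {
  study <- simulate_ciaf_study(seed = 4, rows = 5, cols = 5,
                               children_per_zone = 150)
  zt <- study$zone_table
  w <- study$weights
  spec <- model_spec("SEM", response_transform = "log-rr")
  fit <- fit_model(spec, zt, w)
  expect_s3_class(fit, "model_fit")
  expect_equal(fit$n, 25)
  direct <- fit_spatial("SEM", log(zt$rr),
                        as.matrix(zt[, zone_covariate_columns_test(zt)]), w)
  expect_equal(fit$loglik, direct$loglik, tolerance = 1e-10)
  expect_error(fit_model(model_spec("SAR", lag_covariates = "nope"), zt, w),
               "lag_covariates")
})
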