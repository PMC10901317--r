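## Maximum-likelihood estimation of the nested Gaussian spatial-regression
## family on areal data:
##
##   GNS:  y = rho W y + X beta + W Z theta + u,   u = lambda W u + eps
##
## with eps ~ N(0, sigma2 I). Fixing rho = 0 and/or lambda = 0 and/or
## theta = 0 yields SDM, SDEM, SAC, SAR, SEM, SLX and OLS. Writing
## A = I - rho W and B = I - lambda W, the log-likelihood is
##
##   l = -(n/2) log(2 pi sigma2) + log|A| + log|B|
##       - ||B (A y - X~ gamma)||^2 / (2 sigma2),
##
## X~ = [X, WZ], gamma = (beta, theta). For given spatial coefficients,
## gamma and sigma2 have closed-form maximizers, so estimation reduces to a
## 0-, 1- or 2-dimensional concentrated-likelihood search. log|I - c W| is
## evaluated through the (real) spectrum of the row-standardized W.

.families <- c("OLS", "SLX", "SAR", "SEM", "SDM", "SDEM", "SAC", "GNS")

family_info <- function(family) {
  family <- match.arg(family, .families)
  list(family = family,
       has_rho = family %in% c("SAR", "SDM", "SAC", "GNS"),
       has_lambda = family %in% c("SEM", "SDEM", "SAC", "GNS"),
       has_theta = family %in% c("SLX", "SDM", "SDEM", "GNS"))
}

#' Specify a spatial regression model
#'
#' @param family one of `"OLS"`, `"SLX"`, `"SAR"`, `"SEM"`, `"SDM"`,
#'   `"SDEM"`, `"SAC"`, `"GNS"`.
#' @param lag_covariates names of the covariates entering the spatially
#'   lagged block WZ (default `NULL` = all covariates); ignored by families
#'   without covariate lags.
#' @param response_transform `"log-rr"` (default, `log(y/E)`),
#'   `"prevalence"`, or `"logit-prevalence"`.
#' @param intercept include an intercept (default TRUE).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family,
                       lag_covariates = NULL,
                       response_transform = c("log-rr", "prevalence",
                                              "logit-prevalence"),
                       intercept = TRUE) {
  info <- family_info(family)
  structure(list(family = info$family,
                 lag_covariates = lag_covariates,
                 response_transform = match.arg(response_transform),
                 intercept = isTRUE(intercept)),
            class = "model_spec")
}

#' Admissible interval for a spatial coefficient
#'
#' For row-standardized W the spatial coefficients must lie in
#' `(1/min(eigenvalues), 1)` for `I - c W` to stay positive-determinant;
#' the interval is inset by a small margin for numerical safety.
#'
#' @param w a `spatial_weights` object.
#' @param margin inset from the spectral bounds (default 1e-6).
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
coef_interval <- function(w, margin = 1e-6) {
  w <- ensure_spectrum(w)
  ev <- w$eigenvalues
  lo <- 1 / min(ev)
  c(lo + margin * abs(lo), 1 - margin)
}

#' Log-determinant term of the spatial likelihood
#'
#' `log|I - coef W|` evaluated as `sum(log(1 - coef * omega_i))` over the
#' (real) spectrum of row-standardized W.
#'
#' @param coef spatial coefficient, strictly inside [coef_interval()].
#' @param w a `spatial_weights` object.
#' @return The log-determinant (a real scalar).
#' @export
log_det_term <- function(coef, w) {
  w <- ensure_spectrum(w)
  iv <- coef_interval(w, margin = 0)
  if (!is.finite(coef) || coef <= iv[1] || coef >= iv[2])
    stop("log-determinant undefined: coefficient ", format(coef),
         " outside (", format(iv[1]), ", ", format(iv[2]), ")")
  terms <- 1 - coef * w$eigenvalues
  if (any(terms <= 0))
    stop("log-determinant undefined at coefficient ", format(coef))
  sum(log(terms))
}

## design matrix [intercept | X | WZ], plus bookkeeping
build_design <- function(info, y, X, w, Z = NULL, intercept = TRUE) {
  n <- n_zones(w)
  X <- as.matrix(X)
  if (nrow(X) != n || length(y) != n)
    stop("y and X must be row-aligned with the ", n, " zones of W")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xa <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  if (info$has_theta) {
    Z <- if (is.null(Z)) X else as.matrix(Z)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    WZ <- w$w %*% Z
    colnames(WZ) <- paste0("lag.", colnames(Z))
    Xa <- cbind(Xa, WZ)
  }
  qrX <- qr(Xa)
  if (qrX$rank < ncol(Xa)) {
    drop <- colnames(Xa)[qrX$pivot[(qrX$rank + 1):ncol(Xa)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  Xa
}

## Gaussian profile log-likelihood value from a residual sum of squares
ll_from_rss <- function(rss, n) -(n / 2) * (log(2 * pi * rss / n) + 1)

#' Full negative log-likelihood of a spatial model family
#'
#' Evaluates the (un-concentrated) Gaussian negative log-likelihood at a
#' packed parameter vector `c(gamma, rho?, lambda?, sigma2)`, where `gamma`
#' covers the intercept, covariates and (when present) the lagged-covariate
#' block, and `rho`/`lambda` appear only for families that carry them.
#'
#' @param family model family name.
#' @param params packed parameter vector (see Details above).
#' @param y response vector.
#' @param X covariate matrix (no intercept column).
#' @param w row-standardized `spatial_weights`.
#' @param Z matrix of covariates to lag (default `X`); used only by families
#'   with covariate lags.
#' @param intercept include an intercept (default TRUE).
#' @return The negative log-likelihood (scalar).
#' @export
negative_loglik <- function(family, params, y, X, w, Z = NULL,
                            intercept = TRUE) {
  info <- family_info(family)
  w <- ensure_spectrum(w)
  if (w$style != "row-standardized")
    stop("model likelihoods require row-standardized weights")
  Xa <- build_design(info, y, X, w, Z, intercept)
  p <- ncol(Xa)
  npar <- p + info$has_rho + info$has_lambda + 1L
  if (length(params) != npar)
    stop("expected ", npar, " packed parameters for ", info$family,
         ", got ", length(params))
  gamma <- params[seq_len(p)]
  idx <- p
  rho <- if (info$has_rho) params[idx <- idx + 1L] else 0
  lambda <- if (info$has_lambda) params[idx <- idx + 1L] else 0
  sigma2 <- params[idx + 1L]
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  n <- length(y)
  ld <- 0
  if (info$has_rho) ld <- ld + log_det_term(rho, w)
  if (info$has_lambda) ld <- ld + log_det_term(lambda, w)
  Ay <- y - rho * as.numeric(w$w %*% y)
  u <- Ay - as.numeric(Xa %*% gamma)
  e <- u - lambda * as.numeric(w$w %*% u)
  ll <- -(n / 2) * log(2 * pi * sigma2) + ld - sum(e^2) / (2 * sigma2)
  as.numeric(-ll)
}

## Concentrated-likelihood machinery. All profiles share precomputed
## W y and W Xa so each evaluation is a cheap least-squares solve.
make_profiles <- function(y, Xa, w) {
  W <- w$w
  n <- length(y)
  Wy <- as.numeric(W %*% y)
  WXa <- W %*% Xa
  # SAR-type: regress (y - rho Wy) on Xa; residual is linear in rho
  qrX <- qr(Xa)
  b0 <- qr.coef(qrX, y);  e0 <- y - Xa %*% b0
  bL <- qr.coef(qrX, Wy); eL <- Wy - Xa %*% bL
  prof_lag <- function(rho) {
    rss <- sum((e0 - rho * eL)^2)
    ll_from_rss(rss, n) + log_det_term(rho, w)
  }
  beta_lag <- function(rho) as.numeric(b0 - rho * bL)
  # SEM-type: GLS with filter B = I - lambda W
  prof_err <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- Xa - lambda * WXa
    f <- qr(Xs)
    rss <- sum(qr.resid(f, ys)^2)
    ll_from_rss(rss, n) + log_det_term(lambda, w)
  }
  beta_err <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- Xa - lambda * WXa
    as.numeric(qr.coef(qr(Xs), ys))
  }
  # SAC-type: filter both sides
  prof_sac <- function(rho, lambda) {
    Ay <- y - rho * Wy
    WAy <- as.numeric(W %*% Ay)
    ys <- Ay - lambda * WAy
    Xs <- Xa - lambda * WXa
    f <- qr(Xs)
    rss <- sum(qr.resid(f, ys)^2)
    ll_from_rss(rss, n) + log_det_term(rho, w) + log_det_term(lambda, w)
  }
  beta_sac <- function(rho, lambda) {
    Ay <- y - rho * Wy
    ys <- Ay - lambda * as.numeric(W %*% Ay)
    Xs <- Xa - lambda * WXa
    as.numeric(qr.coef(qr(Xs), ys))
  }
  list(n = n, Wy = Wy, WXa = WXa, qrX = qrX,
       prof_lag = prof_lag, beta_lag = beta_lag,
       prof_err = prof_err, beta_err = beta_err,
       prof_sac = prof_sac, beta_sac = beta_sac)
}

#' Fit a spatial regression model by maximum likelihood
#'
#' OLS and SLX are solved in closed form; SAR/SDM and SEM/SDEM by
#' concentrated likelihood with bounded one-dimensional search over the
#' spatial coefficient; SAC/GNS by bounded quasi-Newton over (rho, lambda)
#' from a deterministic set of starts (center and inset corners of the
#' admissible box, plus the nested one-coefficient optima), keeping the best.
#'
#' @param family model family name (see [model_spec()]).
#' @param y response vector aligned with `w$ids`.
#' @param X covariate matrix (no intercept column).
#' @param w `spatial_weights`; binary weights are row-standardized with a
#'   message.
#' @param Z covariates to lag (default all of `X`).
#' @param intercept include an intercept (default TRUE).
#' @param options list: `tol` for the 1-d search (default 1e-9), `factr` and
#'   `maxit` for the 2-d search.
#' @return A `model_fit` object; see the package vignette for the fields.
#' @export
fit_spatial <- function(family, y, X, w, Z = NULL, intercept = TRUE,
                        options = list()) {
  info <- family_info(family)
  if (w$style != "row-standardized") {
    message("row-standardizing weights for the ", info$family, " likelihood")
    w <- row_standardize(w)
  }
  w <- ensure_spectrum(w)
  y <- as.numeric(y)
  n <- length(y)
  Xa <- build_design(info, y, X, w, Z, intercept)
  p <- ncol(Xa)
  if (n <= p + 3)
    stop("too few zones (n = ", n, ") for ", p, " regression parameters")
  iv <- coef_interval(w)
  pr <- make_profiles(y, Xa, w)
  tol <- options$tol %||% 1e-9
  rho <- lambda <- NULL
  iterations <- 0L
  converged <- TRUE

  if (!info$has_rho && !info$has_lambda) {          # OLS, SLX
    gamma <- as.numeric(qr.coef(pr$qrX, y))
    resid <- as.numeric(qr.resid(pr$qrX, y))
    rss <- sum(resid^2)
    loglik <- ll_from_rss(rss, n)
  } else if (info$has_rho && !info$has_lambda) {    # SAR, SDM
    op <- stats::optimize(pr$prof_lag, interval = iv, maximum = TRUE, tol = tol)
    rho <- op$maximum
    loglik <- op$objective
    gamma <- pr$beta_lag(rho)
  } else if (!info$has_rho && info$has_lambda) {    # SEM, SDEM
    op <- stats::optimize(pr$prof_err, interval = iv, maximum = TRUE, tol = tol)
    lambda <- op$maximum
    loglik <- op$objective
    gamma <- pr$beta_err(lambda)
  } else {                                          # SAC, GNS
    rg <- diff(iv)
    inset <- 0.05 * rg
    corners <- rbind(
      c(iv[1] + inset, iv[1] + inset),
      c(iv[1] + inset, iv[2] - inset),
      c(iv[2] - inset, iv[1] + inset),
      c(iv[2] - inset, iv[2] - inset),
      c(mean(iv), mean(iv))
    )
    # nested one-coefficient optima as deterministic warm starts
    r1 <- stats::optimize(pr$prof_lag, interval = iv, maximum = TRUE, tol = tol)
    l1 <- stats::optimize(pr$prof_err, interval = iv, maximum = TRUE, tol = tol)
    starts <- rbind(corners, c(r1$maximum, 0), c(0, l1$maximum))
    negf <- function(par) -pr$prof_sac(par[1], par[2])
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ], negf, method = "L-BFGS-B",
                        lower = rep(iv[1], 2), upper = rep(iv[2], 2),
                        control = list(factr = options$factr %||% 1e2,
                                       maxit = options$maxit %||% 500))
      iterations <- iterations + o$counts[["function"]]
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (best$convergence != 0)
      converged <- FALSE
    rho <- best$par[1]
    lambda <- best$par[2]
    loglik <- -best$value
    gamma <- pr$beta_sac(rho, lambda)
  }

  rho0 <- rho %||% 0
  lambda0 <- lambda %||% 0
  Ay <- y - rho0 * pr$Wy
  u_hat <- Ay - as.numeric(Xa %*% gamma)
  eps_hat <- u_hat - lambda0 * as.numeric(w$w %*% u_hat)
  sigma2 <- sum(eps_hat^2) / n
  k <- p + 1L + info$has_rho + info$has_lambda
  names(gamma) <- colnames(Xa)
  theta_idx <- grep("^lag\\.", colnames(Xa))
  fit <- structure(list(
    family = info$family,
    info = info,
    beta = gamma[setdiff(seq_len(p), theta_idx)],
    theta = if (length(theta_idx)) gamma[theta_idx] else numeric(0),
    gamma = gamma,
    rho = rho, lambda = lambda, sigma2 = sigma2,
    loglik = loglik, k = k, n = n,
    u_hat = u_hat, eps_hat = eps_hat,
    converged = converged, iterations = iterations,
    rho_interval = iv,
    y = y, design = Xa, ids = w$ids,
    se = NULL, z = NULL, p_value = NULL
  ), class = "model_fit")
  fit <- information_criteria(fit, n)
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(x$family, "fit: loglik =", format(x$loglik, digits = 6),
      " AIC =", format(x$aic, digits = 6),
      " BIC =", format(x$bic, digits = 6), "\n")
  if (!is.null(x$rho)) cat("  rho =", format(x$rho, digits = 4), "\n")
  if (!is.null(x$lambda)) cat("  lambda =", format(x$lambda, digits = 4), "\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' Attach AIC and BIC to a fit
#'
#' `AIC = 2k - 2 loglik`; `BIC = k log(n) - 2 loglik`. The parameter count k
#' includes the regression coefficients, each active spatial coefficient,
#' and sigma2.
#'
#' @param fit a `model_fit`.
#' @param n number of zones.
#' @return `fit` with `aic` and `bic` set.
#' @export
information_criteria <- function(fit, n) {
  fit$aic <- 2 * fit$k - 2 * fit$loglik
  fit$bic <- fit$k * log(n) - 2 * fit$loglik
  fit
}

pack_params <- function(fit) {
  c(fit$gamma,
    if (fit$info$has_rho) fit$rho,
    if (fit$info$has_lambda) fit$lambda,
    fit$sigma2)
}

param_names <- function(fit) {
  c(names(fit$gamma),
    if (fit$info$has_rho) "rho",
    if (fit$info$has_lambda) "lambda",
    "sigma2")
}

## numerical Hessian by central differences, relative step
num_hessian <- function(f, x, rel_step = 1e-5) {
  m <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      ei <- ej <- rep(0, m); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Observed-information standard errors
#'
#' Inverts the numerical Hessian (central differences, relative step 1e-5)
#' of the full negative log-likelihood at the optimum. Adds per-parameter
#' standard errors, z statistics, two-sided normal p-values and significance
#' stars (0.05 / 0.01 / 0.001) to the fit.
#'
#' @param fit a converged `model_fit`.
#' @param w the `spatial_weights` used for the fit.
#' @param rel_step relative finite-difference step (default 1e-5).
#' @return `fit` with `se`, `z`, `p_value`, `stars` and `vcov` set.
#' @export
standard_errors <- function(fit, w, rel_step = 1e-5) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; no standard errors")
  if (w$style != "row-standardized") w <- row_standardize(w)
  w <- ensure_spectrum(w)
  info <- fit$info
  Xa <- fit$design
  y <- fit$y
  n <- fit$n
  Wy <- as.numeric(w$w %*% y)
  nll <- function(par) {
    p <- ncol(Xa)
    gamma <- par[seq_len(p)]
    idx <- p
    rho <- if (info$has_rho) par[idx <- idx + 1L] else 0
    lambda <- if (info$has_lambda) par[idx <- idx + 1L] else 0
    sigma2 <- par[idx + 1L]
    if (sigma2 <= 0) return(Inf)
    ld <- 0
    if (info$has_rho) ld <- ld + log_det_term(rho, w)
    if (info$has_lambda) ld <- ld + log_det_term(lambda, w)
    u <- (y - rho * Wy) - as.numeric(Xa %*% gamma)
    e <- u - lambda * as.numeric(w$w %*% u)
    (n / 2) * log(2 * pi * sigma2) - ld + sum(e^2) / (2 * sigma2)
  }
  par <- pack_params(fit)
  H <- num_hessian(nll, par, rel_step)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("non-positive-definite Hessian: flat or boundary optimum ",
         "(weakly identified ", fit$family, " fit)")
  if (fit$family == "GNS" && max(ev) / min(ev) > 1e8)
    warning("GNS fit is weakly identified (Hessian condition number > 1e8); ",
            "interpret rho, lambda and theta with caution")
  V <- solve(H)
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- param_names(fit)
  z <- par / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  fit$vcov <- V
  fit$se <- se
  fit$z <- z
  fit$p_value <- p
  fit$stars <- significance_stars(p)
  fit
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#' @param p vector of p-values.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

## response construction from a zone table
response_vector <- function(zt, transform) {
  switch(transform,
    "log-rr" = {
      if (!"rr" %in% names(zt)) stop("zone table lacks rr; run crude_relative_risk")
      if (any(zt$y == 0))
        stop("log-rr response undefined: zero CIAF count in zone(s) ",
             paste(zt$zone_id[zt$y == 0], collapse = ", "))
      log(zt$rr)
    },
    "prevalence" = zt$prevalence,
    "logit-prevalence" = {
      if (any(zt$prevalence <= 0 | zt$prevalence >= 1))
        stop("logit-prevalence undefined for prevalence 0 or 1")
      stats::qlogis(zt$prevalence)
    },
    stop("unknown response transform: ", transform)
  )
}

zone_covariate_columns <- function(zt) {
  setdiff(names(zt), c("zone_id", "n", "y", "prevalence", "E", "rr"))
}

#' Fit a model specification to a zone table
#'
#' Builds the response from the zone table per the spec's transform, takes
#' every non-reserved column as a covariate, and dispatches to
#' [fit_spatial()].
#'
#' @param spec a [model_spec()].
#' @param zt zone table (with `rr` for the log-rr response); covariates are
#'   all columns other than `zone_id`, `n`, `y`, `prevalence`, `E`, `rr`.
#' @param w `spatial_weights`; `zt$zone_id` must equal `w$ids` in order.
#' @param options optimizer options passed to [fit_spatial()].
#' @return A `model_fit`.
#' @export
fit_model <- function(spec, zt, w, options = list()) {
  stopifnot(inherits(spec, "model_spec"))
  if (!identical(as.character(zt$zone_id), w$ids))
    stop("zone table and weights disagree on zone ids or their order")
  y <- response_vector(zt, spec$response_transform)
  covs <- zone_covariate_columns(zt)
  if (!length(covs)) stop("zone table has no covariate columns")
  X <- as.matrix(zt[, covs, drop = FALSE])
  lagc <- spec$lag_covariates %||% covs
  bad <- setdiff(lagc, covs)
  if (length(bad))
    stop("lag_covariates not in the covariate set: ", paste(bad, collapse = ", "))
  Z <- X[, lagc, drop = FALSE]
  fit <- fit_spatial(spec$family, y, X, w, Z = Z,
                     intercept = spec$intercept, options = options)
  fit$spec <- spec
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
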