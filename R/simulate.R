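## Synthetic-data generators: grid lattices, spatially smoothed covariates,
## model-based responses with known parameters, and child-level survey-like
## anthropometric records. Every generator is a pure function of its
## arguments and seed, so all fixtures are reproducible in code.

#' Unit-square grid lattice with contiguity weights
#'
#' Zones are unit squares with deterministic ids `"r{i}c{j}"` (row-major
#' order); weights come from [contiguity_from_polygons()].
#'
#' @param rows,cols grid dimensions (each at least 2).
#' @param rule contiguity rule, `"queen"` or `"rook"`.
#' @return List with `geometries` (named list of ring matrices) and
#'   `weights` (binary [spatial_weights()]).
#' @export
make_grid_lattice <- function(rows, cols, rule = c("queen", "rook")) {
  rule <- match.arg(rule)
  if (rows < 2 || cols < 2) stop("rows and cols must be at least 2")
  geoms <- list()
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      x0 <- j - 1; y0 <- rows - i   # row 1 on top, map-style
      geoms[[sprintf("r%dc%d", i, j)]] <- rbind(
        c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1), c(x0, y0)
      )
    }
  }
  list(geometries = geoms,
       weights = contiguity_from_polygons(geoms, rule = rule))
}

#' Spatially autocorrelated covariates
#'
#' Each column is `(I - phi W)^-1 eps` with `eps` i.i.d. standard normal,
#' then affinely mapped to a percentage-like scale (the affine constants are
#' recorded as attributes). `phi = 0` gives independent noise.
#'
#' @param w row-standardized `spatial_weights` (binary is standardized
#'   automatically).
#' @param p number of covariates.
#' @param phi spatial smoothing coefficient, inside [coef_interval()].
#' @param seed integer seed.
#' @param means,sds targets for the affine percentage mapping (recycled to
#'   length `p`; defaults 50 and 12).
#' @return n x p covariate matrix with columns `cov1..covp`.
#' @export
simulate_covariates <- function(w, p, phi, seed, means = 50, sds = 12) {
  if (w$style != "row-standardized") w <- row_standardize(w)
  w <- ensure_spectrum(w)
  iv <- coef_interval(w, margin = 0)
  if (phi != 0 && (phi <= iv[1] || phi >= iv[2]))
    stop("phi outside the admissible interval (", format(iv[1]), ", ",
         format(iv[2]), ")")
  n <- n_zones(w)
  means <- rep_len(means, p)
  sds <- rep_len(sds, p)
  set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(n * p), n, p)
  M <- if (phi == 0) eps else solve(diag(n) - phi * w$w, eps)
  M <- scale(M)  # standardize, then map to percentage-like ranges
  X <- sweep(sweep(M, 2, sds, `*`), 2, means, `+`)
  colnames(X) <- paste0("cov", seq_len(p))
  rownames(X) <- w$ids
  attr(X, "affine") <- list(means = means, sds = sds)
  X
}

#' Simulate a response from one of the spatial data-generating processes
#'
#' Exact reduced-form sampling: `eps ~ N(0, sigma^2 I)`,
#' `u = (I - lambda W)^-1 eps`, `y = (I - rho W)^-1 (X beta + W Z theta + u)`,
#' with `rho`, `lambda`, `theta` zeroed for families that lack them. Dense
#' solves are used throughout (zone counts are desk-scale).
#'
#' @param family DGP family name (same eight as the fitters).
#' @param w row-standardized `spatial_weights`.
#' @param X covariate matrix (no intercept column).
#' @param params list with `beta` (includes intercept as first element),
#'   `theta` (optional), `rho`, `lambda`, `sigma`.
#' @param seed integer seed (ignored when `sigma = 0`).
#' @param Z covariates to lag (default `X`).
#' @return Numeric response vector of length n.
#' @export
simulate_response <- function(family, w, X, params, seed, Z = NULL) {
  info <- family_info(family)
  if (w$style != "row-standardized") w <- row_standardize(w)
  w <- ensure_spectrum(w)
  n <- n_zones(w)
  X <- as.matrix(X)
  Xa <- cbind(1, X)
  beta <- params$beta
  if (length(beta) != ncol(Xa))
    stop("beta must have length ", ncol(Xa), " (intercept first)")
  rho <- if (info$has_rho) params$rho %||% 0 else 0
  lambda <- if (info$has_lambda) params$lambda %||% 0 else 0
  sigma <- params$sigma %||% 1
  iv <- coef_interval(w, margin = 0)
  for (cf in c(rho, lambda))
    if (cf != 0 && (cf <= iv[1] || cf >= iv[2]))
      stop("inadmissible spatial coefficient ", format(cf))
  mean_part <- as.numeric(Xa %*% beta)
  if (info$has_theta) {
    Z <- if (is.null(Z)) X else as.matrix(Z)
    theta <- params$theta %||% rep(0, ncol(Z))
    if (length(theta) != ncol(Z)) stop("theta must match ncol(Z)")
    mean_part <- mean_part + as.numeric((w$w %*% Z) %*% theta)
  }
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) {
    u <- rep(0, n)
  } else {
    set.seed(as.integer(seed))
    eps <- stats::rnorm(n, 0, sigma)
    u <- if (lambda == 0) eps else solve(diag(n) - lambda * w$w, eps)
  }
  rhs <- mean_part + u
  y <- if (rho == 0) rhs else solve(diag(n) - rho * w$w, rhs)
  as.numeric(y)
}

## default anthropometric z-score correlation: HAZ-WAZ and WAZ-WHZ strongly
## positive, HAZ-WHZ nearly independent (typical survey pattern)
default_zscore_corr <- function() {
  m <- matrix(c(1, 0.6, 0.1,
                0.6, 1, 0.6,
                0.1, 0.6, 1), 3, 3)
  dimnames(m) <- list(c("haz", "waz", "whz"), c("haz", "waz", "whz"))
  m
}

#' Simulate a child-level anthropometric survey
#'
#' Children in zone i draw `(haz, waz, whz)` from a trivariate normal with
#' common mean shift `zone_effects[i]` on all three scores and the given
#' correlation. Lower shifts produce higher CIAF prevalence; spatially
#' smoothed shifts produce spatially clustered prevalence.
#'
#' @param zone_effects named numeric vector of per-zone mean shifts (names
#'   are the zone ids).
#' @param n_per_zone children per zone (scalar or per-zone vector).
#' @param zscore_corr 3x3 positive-definite correlation matrix for
#'   (haz, waz, whz); default [default_zscore_corr()].
#' @param seed integer seed.
#' @return Data frame of child records: `child_id`, `zone_id`, `haz`, `waz`,
#'   `whz`.
#' @export
simulate_child_survey <- function(zone_effects, n_per_zone,
                                  zscore_corr = default_zscore_corr(),
                                  seed = 1) {
  ids <- names(zone_effects)
  if (is.null(ids)) stop("zone_effects must be named by zone id")
  if (any(n_per_zone < 1)) stop("n_per_zone must be at least 1")
  n_per_zone <- rep_len(as.integer(n_per_zone), length(ids))
  zscore_corr <- as.matrix(zscore_corr)
  ch <- tryCatch(chol(zscore_corr),
                 error = function(e) stop("zscore_corr is not positive definite"))
  set.seed(as.integer(seed))
  total <- sum(n_per_zone)
  E <- matrix(stats::rnorm(total * 3), total, 3) %*% ch
  zone_col <- rep(ids, n_per_zone)
  shift <- rep(as.numeric(zone_effects), n_per_zone)
  data.frame(
    child_id = sprintf("c%06d", seq_len(total)),
    zone_id = zone_col,
    haz = E[, 1] + shift,
    waz = E[, 2] + shift,
    whz = E[, 3] + shift,
    stringsAsFactors = FALSE
  )
}

#' Parameter-recovery experiment for the spatial estimators
#'
#' Repeatedly simulates from a chosen DGP, refits it, and aggregates bias,
#' RMSE and 95% Wald coverage per parameter. Per-replicate seeds are derived
#' deterministically from the master seed.
#'
#' @param family DGP and fitting family.
#' @param w `spatial_weights` for the lattice.
#' @param true_params list as in [simulate_response()] (plus `theta` when
#'   applicable).
#' @param X fixed covariate matrix (one draw is made if `NULL`: standard
#'   normal, `length(beta) - 1` columns).
#' @param nreps number of replicates (at least 50).
#' @param seed master integer seed.
#' @param max_fail_rate error if more than this fraction of replicates fails
#'   to converge (default 0.1).
#' @return Data frame: one row per parameter with truth, mean estimate,
#'   bias, RMSE and coverage; attribute `"n_failed"`.
#' @export
recovery_experiment <- function(family, w, true_params, X = NULL,
                                nreps = 200, seed = 1, max_fail_rate = 0.1) {
  if (nreps < 50) stop("nreps must be at least 50")
  if (w$style != "row-standardized") w <- row_standardize(w)
  w <- ensure_spectrum(w)
  n <- n_zones(w)
  pbeta <- length(true_params$beta)
  if (is.null(X)) {
    set.seed(as.integer(seed))
    X <- matrix(stats::rnorm(n * (pbeta - 1)), n, pbeta - 1)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  info <- family_info(family)
  truth <- c(setNames(true_params$beta,
                      c("(Intercept)", colnames(X))),
             if (info$has_theta)
               setNames(true_params$theta %||% rep(0, ncol(X)),
                        paste0("lag.", colnames(X))),
             if (info$has_rho) c(rho = true_params$rho),
             if (info$has_lambda) c(lambda = true_params$lambda),
             sigma2 = (true_params$sigma %||% 1)^2)
  est <- cov_hit <- matrix(NA_real_, nreps, length(truth),
                           dimnames = list(NULL, names(truth)))
  failed <- 0L
  for (r in seq_len(nreps)) {
    yr <- simulate_response(family, w, X, true_params, seed = seed + r)
    fit <- tryCatch({
      f <- fit_spatial(family, yr, X, w)
      standard_errors(f, w)
    }, error = function(e) NULL, warning = function(wn) {
      f <- suppressWarnings(standard_errors(fit_spatial(family, yr, X, w), w))
      f
    })
    if (is.null(fit) || !isTRUE(fit$converged)) { failed <- failed + 1L; next }
    pk <- pack_params(fit)
    names(pk) <- param_names(fit)
    pk <- pk[names(truth)]
    se <- fit$se[names(truth)]
    est[r, ] <- pk
    cov_hit[r, ] <- abs(pk - truth) <= stats::qnorm(0.975) * se
  }
  if (failed > max_fail_rate * nreps)
    stop("non-convergence in ", failed, "/", nreps, " replicates")
  ok <- stats::complete.cases(est)
  out <- data.frame(
    parameter = names(truth),
    truth = unname(truth),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(truth),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            matrix(truth, sum(ok), length(truth),
                                   byrow = TRUE))^2)),
    coverage = colMeans(cov_hit[ok, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_failed") <- failed
  out
}

#' Generate the full synthetic zone study (the package's stand-in fixture
#' for the restricted survey microdata)
#'
#' Builds a 72-zone lattice (9 x 8 unit squares, queen contiguity by
#' default), spatially smoothed percentage covariates, a relative-risk
#' surface from a chosen spatial DGP on the standardized covariates, zone
#' CIAF counts consistent with that surface, and a child-level survey whose
#' zone mean shifts reproduce the zone prevalences. All true parameters are
#' returned in `truth`.
#'
#' @param seed master integer seed.
#' @param rows,cols lattice dimensions (default 9 x 8 = 72 zones).
#' @param rule contiguity rule (default queen).
#' @param family DGP family for the risk surface (default `"SAC"`).
#' @param rho,lambda,sigma DGP spatial coefficients and error SD (defaults
#'   0.4, 0.4, 0.15).
#' @param beta coefficients on the standardized covariates, intercept first
#'   (default `c(0, 0.15, -0.12, 0.1, -0.08, 0.12, -0.06)` for 6 covariates).
#' @param phi covariate spatial smoothing (default 0.6).
#' @param children_per_zone children simulated per zone (default 200).
#' @param baseline_prev overall CIAF prevalence anchor (default 0.45,
#'   a realistic national under-five figure for the emulated setting).
#' @return List: `children`, `zone_table` (with covariates, E, rr),
#'   `weights`, `geometries`, `truth`.
#' @export
simulate_ciaf_study <- function(seed = 1, rows = 9, cols = 8,
                                rule = "queen", family = "SAC",
                                rho = 0.4, lambda = 0.4, sigma = 0.15,
                                beta = c(0, 0.15, -0.12, 0.1, -0.08, 0.12, -0.06),
                                phi = 0.6, children_per_zone = 200,
                                baseline_prev = 0.45) {
  lat <- make_grid_lattice(rows, cols, rule = rule)
  w <- row_standardize(lat$weights)
  p <- length(beta) - 1
  X <- simulate_covariates(w, p, phi, seed = seed)
  covnames <- c("mother_illiteracy", "unimproved_water", "low_bmi_mothers",
                "child_comorbidity", "max_temperature", "min_temperature")
  colnames(X) <- if (p <= length(covnames)) covnames[seq_len(p)] else
    paste0("cov", seq_len(p))
  Xs <- scale(X)
  eta <- simulate_response(family, w, Xs,
                           params = list(beta = beta, rho = rho,
                                         lambda = lambda, sigma = sigma,
                                         theta = rep(0.05, p)),
                           seed = seed + 1000L)
  # log relative-risk surface; cap so zone prevalence stays inside (0, 1)
  gamma_i <- exp(eta - mean(eta))
  prev <- pmin(0.95, pmax(0.02, baseline_prev * gamma_i))
  names(prev) <- w$ids
  # child-level records: common mean shift per zone chosen so the marginal
  # failure probability matches the zone prevalence (monotone inversion)
  prev_of_shift <- function(m) {
    # P(at least one z < -2) under the default correlation, via the
    # one-factor structure of the generator (numerical integration over
    # the shared shift is unnecessary: inverted by simulation-free
    # monotone bisection on the independent-approximation, then corrected
    # at the aggregate level through the observed counts)
    1 - stats::pnorm(2 + m)^3
  }
  shift <- vapply(prev, function(p_i) {
    stats::uniroot(function(m) prev_of_shift(m) - p_i,
                   interval = c(-6, 6), tol = 1e-10)$root
  }, numeric(1))
  children <- simulate_child_survey(shift, children_per_zone, seed = seed + 2000L)
  classified <- classify_children(children)
  zt <- aggregate_zones(classified)
  zt <- expected_counts(zt)
  zt <- crude_relative_risk(zt)
  zt <- cbind(zt, as.data.frame(X)[match(zt$zone_id, rownames(X)), ,
                                   drop = FALSE])
  rownames(zt) <- NULL
  list(children = children,
       zone_table = zt,
       weights = w,
       geometries = lat$geometries,
       truth = list(family = family, rho = rho, lambda = lambda,
                    sigma = sigma, beta = beta, phi = phi,
                    baseline_prev = baseline_prev, seed = seed,
                    prevalence = prev, eta = eta))
}
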