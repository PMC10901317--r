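## Global and local Moran's I with analytic and permutation inference.
##
## I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2.
## Under the no-association null E[I] = -1/(n-1). Analytic variances follow
## the classical normality and randomization (permutation-moment) formulas;
## permutation inference reshuffles x over the zones.

moran_core <- function(z, w) {
  # returns list(I, num, denom) for centered z
  lag <- w$w %*% z
  num <- sum(z * lag)
  denom <- sum(z^2)
  list(I = (length(z) / w$s0) * num / denom, num = num, denom = denom)
}

moran_check <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- n_zones(w)
  if (length(x) != n)
    stop("length(x) = ", length(x), " does not match the ", n, " zones of W")
  if (n < 3) stop("need at least 3 zones")
  if (!all(is.finite(x))) stop("x must be finite")
  if (stats::sd(x) == 0) stop("no variance: x is constant")
  invisible(n)
}

#' Global Moran's I
#'
#' @param x numeric vector, one value per zone, in the row order of `w$ids`.
#' @param w a [spatial_weights()] object (either style; the statistic's
#'   `n/S0` prefactor handles both).
#' @param inference `"permutation"` (default), `"randomization"` or
#'   `"normality"`. The analytic two-sided p is always reported alongside.
#' @param nperm number of permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @param alternative direction for the pseudo p-value: `"folded"` (default;
#'   one-sided toward the observed side of E\[I\]), `"greater"`, `"less"`, or
#'   `"two.sided"` (doubled folded tail, capped at 1).
#' @return A `moran_result` list: `I`, `expected`, `variance`, `z_score`,
#'   `p_analytic`, `p_pseudo`, `nperm`, `seed`, `mu`, `perm_mean`, `perm_sd`.
#' @export
global_moran <- function(x, w,
                         inference = c("permutation", "randomization", "normality"),
                         nperm = 999, seed = 1,
                         alternative = c("folded", "greater", "less", "two.sided")) {
  inference <- match.arg(inference)
  alternative <- match.arg(alternative)
  n <- moran_check(x, w)
  mu <- mean(x)
  z <- x - mu
  obs <- moran_core(z, w)
  I <- obs$I
  expected <- -1 / (n - 1)

  W <- w$w
  s0 <- w$s0
  s1 <- 0.5 * sum((W + t(W))^2)
  s2 <- sum((rowSums(W) + colSums(W))^2)
  var_norm <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - expected^2
  b2 <- n * sum(z^4) / (sum(z^2))^2
  var_rand <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
                 b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - expected^2

  perm_mean <- perm_sd <- p_pseudo <- NA_real_
  variance <- switch(inference,
                     normality = var_norm,
                     randomization = var_rand,
                     permutation = NA_real_)
  if (inference == "permutation") {
    if (nperm < 1) stop("nperm must be >= 1")
    set.seed(as.integer(seed))
    P <- matrix(0, n, nperm)
    for (b in seq_len(nperm)) P[, b] <- z[sample.int(n)]
    num_perm <- colSums(P * (W %*% P))
    I_perm <- (n / s0) * num_perm / obs$denom
    perm_mean <- mean(I_perm)
    perm_sd <- stats::sd(I_perm)
    variance <- perm_sd^2
    p_up <- (sum(I_perm >= I) + 1) / (nperm + 1)
    p_lo <- (sum(I_perm <= I) + 1) / (nperm + 1)
    p_pseudo <- switch(alternative,
                       greater = p_up,
                       less = p_lo,
                       folded = if (I >= expected) p_up else p_lo,
                       two.sided = min(1, 2 * min(p_up, p_lo)))
  }
  sd_a <- sqrt(if (inference == "normality") var_norm else var_rand)
  z_score <- (I - expected) / (if (inference == "permutation" && is.finite(perm_sd))
    perm_sd else sd_a)
  p_analytic <- 2 * stats::pnorm(abs((I - expected) / sd_a), lower.tail = FALSE)

  structure(list(I = I, expected = expected, variance = variance,
                 z_score = z_score, p_analytic = p_analytic,
                 p_pseudo = p_pseudo, nperm = if (inference == "permutation") nperm else 0L,
                 seed = seed, mu = mu, inference = inference,
                 alternative = alternative,
                 perm_mean = perm_mean, perm_sd = perm_sd, n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat("Global Moran's I =", format(x$I, digits = 4),
      " E[I] =", format(x$expected, digits = 4),
      " z =", format(x$z_score, digits = 3), "\n")
  cat("  analytic p =", format(x$p_analytic, digits = 3), "\n")
  if (!is.na(x$p_pseudo))
    cat("  pseudo p =", format(x$p_pseudo, digits = 3),
        "(", x$nperm, "permutations, seed", x$seed, ",", x$alternative, ")\n")
  invisible(x)
}

#' Moran scatter: centered values, spatial lags and quadrants
#'
#' With row-standardized weights, the least-squares slope of the lag on the
#' centered value equals global Moran's I.
#'
#' @inheritParams global_moran
#' @return Data frame with `zone_id`, `z` (centered value), `lag`, and
#'   `quadrant` (HH/LL/HL/LH).
#' @export
moran_scatter <- function(x, w) {
  moran_check(x, w)
  if (w$style != "binary" && w$style != "row-standardized")
    stop("unknown weights style")
  if (w$style == "binary") {
    message("row-standardizing weights for the Moran scatter")
    w <- row_standardize(w)
  }
  z <- x - mean(x)
  lag <- as.numeric(w$w %*% z)
  quadrant <- ifelse(z >= 0 & lag >= 0, "HH",
              ifelse(z < 0 & lag < 0, "LL",
              ifelse(z >= 0, "HL", "LH")))
  data.frame(zone_id = w$ids, z = z, lag = lag, quadrant = quadrant,
             stringsAsFactors = FALSE)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' `I_i = (z_i / m2) * sum_j w_ij z_j` with `m2 = sum(z^2)/n`; the local
#' statistics sum to `S0 * I_global`. Inference holds the value at zone i
#' fixed and permutes the remaining n-1 values into its neighbors'
#' positions; the pseudo p is one-sided toward the observed side of the
#' zone's permutation mean.
#'
#' @inheritParams global_moran
#' @return Data frame with `zone_id`, `I_i`, `quadrant`, `p_pseudo`.
#' @export
local_moran <- function(x, w, nperm = 999, seed = 1) {
  n <- moran_check(x, w)
  if (w$style == "binary") {
    message("row-standardizing weights for LISA")
    w <- row_standardize(w)
  }
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- as.numeric(w$w %*% z)
  I_i <- z * lag / m2
  quadrant <- ifelse(z >= 0 & lag >= 0, "HH",
              ifelse(z < 0 & lag < 0, "LL",
              ifelse(z >= 0, "HL", "LH")))
  p <- numeric(n)
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    wi <- w$w[i, ]
    nb <- which(wi > 0)
    if (!length(nb)) { p[i] <- NA_real_; next }
    pool <- z[-i]
    draws <- matrix(0, nperm, length(nb))
    for (b in seq_len(nperm))
      draws[b, ] <- pool[sample.int(length(pool), length(nb))]
    lag_perm <- as.numeric(draws %*% wi[nb])
    I_perm <- z[i] * lag_perm / m2
    if (I_i[i] >= mean(I_perm))
      p[i] <- (sum(I_perm >= I_i[i]) + 1) / (nperm + 1)
    else
      p[i] <- (sum(I_perm <= I_i[i]) + 1) / (nperm + 1)
  }
  data.frame(zone_id = w$ids, I_i = I_i, quadrant = quadrant,
             p_pseudo = p, stringsAsFactors = FALSE)
}

#' Label LISA records as hot spots, cold spots, outliers or not significant
#'
#' @param lisa output of [local_moran()].
#' @param alpha significance level (default 0.05, the level used for the
#'   cluster maps).
#' @param correction `"none"` (default) or `"fdr"` (Benjamini-Hochberg on the
#'   pseudo p-values before thresholding).
#' @return `lisa` with an added `cluster` column: `high-high`, `low-low`,
#'   `high-low`, `low-high`, or `not-significant`.
#' @export
classify_clusters <- function(lisa, alpha = 0.05, correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  stopifnot(all(c("quadrant", "p_pseudo") %in% names(lisa)))
  p <- lisa$p_pseudo
  if (correction == "fdr") p <- stats::p.adjust(p, method = "BH")
  lab <- c(HH = "high-high", LL = "low-low", HL = "high-low", LH = "low-high")
  lisa$cluster <- ifelse(!is.na(p) & p <= alpha,
                         lab[lisa$quadrant], "not-significant")
  lisa
}
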