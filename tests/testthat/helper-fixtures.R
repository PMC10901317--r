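# Shared fixtures and independent oracles for the test suite.

# literal two-nested-loop evaluation of the Moran statistic
moran_brute <- function(x, W, s0 = sum(W)) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + W[i, j] * z[i] * z[j]
  (n / s0) * num / sum(z^2)
}

# random connected symmetric binary graph: spanning path over a shuffled
# order plus independent extra edges
random_connected_weights <- function(n, p_extra = 0.25) {
  ids <- sprintf("z%02d", seq_len(n))
  ord <- sample(n)
  edges <- cbind(ids[ord[-n]], ids[ord[-1]])
  extra <- which(upper.tri(matrix(0, n, n)) &
                   matrix(runif(n * n) < p_extra, n, n), arr.ind = TRUE)
  if (nrow(extra))
    edges <- rbind(edges, cbind(ids[extra[, 1]], ids[extra[, 2]]))
  from_edge_list(edges, ids)
}

path_weights <- function(ids) {
  from_edge_list(cbind(ids[-length(ids)], ids[-1]), ids)
}

# frozen n = 6 path-graph toy instance (ids a-f, one covariate)
toy6 <- function() {
  ids <- letters[1:6]
  list(
    ids = ids,
    w = row_standardize(path_weights(ids)),
    x1 = c(-0.591031, 0.026594, -1.516553, -1.362653, 1.178489, -0.934151),
    y = c(-0.677048, 1.125950, -1.846266, -1.925909, -0.249993, -0.724756)
  )
}

# dense, fully independent evaluation of the GNS-family log-likelihood
loglik_dense <- function(y, Xa, W, gamma, rho, lambda, sigma2) {
  n <- length(y)
  A <- diag(n) - rho * W
  B <- diag(n) - lambda * W
  e <- B %*% (A %*% y - Xa %*% gamma)
  as.numeric(-(n / 2) * log(2 * pi * sigma2) +
               determinant(A)$modulus + determinant(B)$modulus -
               crossprod(e) / (2 * sigma2))
}

all_families <- c("OLS", "SLX", "SAR", "SEM", "SDM", "SDEM", "SAC", "GNS")

zone_covariate_columns_test <- function(zt)
  setdiff(names(zt), c("zone_id", "n", "y", "prevalence", "E", "rr"))
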