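# Independent oracles and small fixture generators used across the suite.
# Every oracle is a separate computational route from the implementation it
# checks (covariance-form GLS vs the bordered semivariogram solver, explicit
# loops vs vectorized binning, plain solve()/det() vs Cholesky identities).

# small irregular dataset on a compact box; a thin wrapper around the
# package generator with toy-sized defaults
toy_dataset <- function(n = 15, seed = 1, family = "spherical", sill = 0.7,
                        range_ = 1.2, nugget = 0.4, bbox = c(0, 3, 0, 3),
                        beta = NULL, degree = 1L, lambda_back = -0.028) {
  tr <- trendSpec(degree)
  if (is.null(beta)) beta <- c(5, rep(0.2, trendRank(tr) - 1L))
  simulateGRF(simulationSpec(
    bbox = bbox, nSites = n, beta = beta,
    model = variogramModel(family, sill, range_, nugget),
    trend = tr, lambdaBack = lambda_back, seed = seed))
}

# universal kriging via the covariance-form GLS equations:
# Yhat(x0) = f0' bhat + c0' Sigma^-1 (Y - F bhat), and the standard variance
# sigma2(x0) - c0' Sigma^-1 c0 + d' (F' Sigma^-1 F)^-1 d, d = f0 - F' Si c0.
# Implemented with plain solve(), independent of the bordered solver.
gls_uk_oracle <- function(data, model, trend, target) {
  y <- tvalues(data)
  xy <- coords(data)
  F <- designMatrix(trend, xy[, 1], xy[, 2])
  S <- covarianceMatrix(model, xy[, 1], xy[, 2])
  h0 <- sqrt((xy[, 1] - target[1])^2 + (xy[, 2] - target[2])^2)
  c0 <- covariance(model, h0)
  f0 <- as.numeric(designMatrix(trend, target[1], target[2]))
  Si <- solve(S)
  A <- solve(t(F) %*% Si %*% F)
  bhat <- A %*% t(F) %*% Si %*% y
  m <- as.numeric(t(f0) %*% bhat + t(c0) %*% Si %*% (y - F %*% bhat))
  d <- f0 - as.numeric(t(F) %*% Si %*% c0)
  v <- model@sigma2 - as.numeric(t(c0) %*% Si %*% c0) +
    as.numeric(t(d) %*% A %*% d)
  list(mean = m, variance = v)
}

# leave-one-out by rebuilding the full system per fold through the GLS oracle
naive_loocv <- function(data, model, trend) {
  n <- nSites(data)
  xy <- coords(data)
  sapply(seq_len(n), function(i) {
    di <- geoDataset(xy[-i, 1], xy[-i, 2], values(data)[-i],
                     tvalue = tvalues(data)[-i])
    gls_uk_oracle(di, model, trend, xy[i, ])$mean
  })
}

# Matheron estimator by explicit O(n^2) pair enumeration
brute_variogram <- function(data, trend, nbins, maxDist) {
  r <- stats::lm.fit(designMatrix(trend, data@lat, data@lon),
                     tvalues(data))$residuals
  n <- nSites(data)
  breaks <- seq(0, maxDist, length.out = nbins + 1)
  num <- den <- numeric(nbins)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    h <- sqrt((data@lat[i] - data@lat[j])^2 + (data@lon[i] - data@lon[j])^2)
    if (h <= 0 || h > maxDist) next
    k <- min(max(findInterval(h, breaks, rightmost.closed = TRUE), 1), nbins)
    num[k] <- num[k] + (r[i] - r[j])^2
    den[k] <- den[k] + 1
  }
  keep <- den > 0
  list(gamma = (num[keep] / (2 * den[keep])), counts = den[keep],
       centers = ((breaks[-1] + breaks[-(nbins + 1)]) / 2)[keep])
}

# direct evaluation of the discrete posterior over (tau2, alpha) with plain
# solve()/determinant(), bypassing the package's Cholesky statistics
posterior_oracle <- function(data, trend, family, tau2, alpha, prior) {
  y <- tvalues(data)
  xy <- coords(data)
  F <- designMatrix(trend, xy[, 1], xy[, 2])
  n <- length(y); p <- ncol(F)
  D <- as.matrix(stats::dist(xy))
  lp <- mapply(function(t2, a) {
    R <- (1 - t2) * corrFunction(family, D, a); diag(R) <- 1
    Ri <- solve(R)
    A <- t(F) %*% Ri %*% F
    bhat <- solve(A, t(F) %*% Ri %*% y)
    r <- y - F %*% bhat
    S2 <- as.numeric(t(r) %*% Ri %*% r) / (n - p)
    -0.5 * as.numeric(determinant(R)$modulus) -
      0.5 * as.numeric(determinant(A)$modulus) - (n - p) / 2 * log(S2)
  }, tau2, alpha)
  w <- prior * exp(lp - max(lp))
  w / sum(w)
}

expect_design_valid <- function(d) expect_true(isTRUE(validObject(d, test = TRUE)))
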