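test_that("S2 vanishes on exact trend data and reduces to the OLS MSE", {
  tr <- trendSpec(1L)
  lat <- runif(10, 0, 3); lon <- runif(10, 0, 3)
  F <- designMatrix(tr, lat, lon)
  y_exact <- as.numeric(F %*% c(2, 0.3, -0.1))
  d <- geoDataset(lat, lon, exp(y_exact), tvalue = y_exact)
  expect_lt(as.numeric(s2Stat(d, tr, "spherical", 0.4, 1)), 1e-18)

  # far-apart sites with a spherical model: R = I exactly, so S2 is the
  # classical residual mean square with divisor n - p
  lat2 <- seq(0, 90, by = 10)
  lon2 <- c(15, 470, 230, 640, 90, 333, 555, 760, 412, 871)
  y2 <- rnorm(10, 5, 1)
  d2 <- geoDataset(lat2, lon2, exp(y2 / 10), tvalue = y2)
  s2 <- as.numeric(s2Stat(d2, tr, "spherical", 0, 1))
  ols <- sum(lm(y2 ~ lat2 + lon2)$residuals^2) / (10 - 3)
  expect_equal(s2, ols, tolerance = 1e-10)
})

test_that("S2 matches a direct normal-equations oracle", {
  d <- toy_dataset(n = 10, seed = 41)
  tr <- trendSpec(1L)
  xy <- coords(d); y <- tvalues(d)
  F <- designMatrix(tr, xy[, 1], xy[, 2])
  D <- as.matrix(dist(xy))
  R <- (1 - 0.3) * corrFunction("spherical", D, 1.4); diag(R) <- 1
  Ri <- solve(R)
  bhat <- solve(t(F) %*% Ri %*% F, t(F) %*% Ri %*% y)
  r <- y - F %*% bhat
  S2_oracle <- as.numeric(t(r) %*% Ri %*% r) / (10 - 3)
  s2 <- s2Stat(d, tr, "spherical", 0.3, 1.4)
  expect_equal(as.numeric(s2), S2_oracle, tolerance = 1e-10)
  expect_equal(attr(s2, "betaHat"), as.numeric(bhat), tolerance = 1e-10)
})

test_that("degenerate and symmetric priors behave as forced", {
  d <- toy_dataset(n = 12, seed = 43)
  tr <- trendSpec(1L)
  pg1 <- posteriorWeights(d, tr, "spherical", priorGrid(1.2, 0.3))
  expect_equal(pg1@post, 1)
  # two support points whose correlation matrices coincide: a spherical
  # model is pure nugget at any range shorter than the minimum distance
  dmin <- min(dist(coords(d)))
  pg2 <- posteriorWeights(d, tr, "spherical",
    priorGrid(alpha = c(dmin * 0.5, dmin * 0.25), tau2rel = 0.2,
              prior = c(0.3, 0.7), expand = FALSE))
  expect_equal(pg2@post, pg2@prior, tolerance = 1e-10)
})

test_that("posterior weights match the direct-evaluation oracle", {
  d <- toy_dataset(n = 12, seed = 47)
  tr <- trendSpec(1L)
  tau2 <- c(0.1, 0.4, 0.7); alpha <- c(0.8, 1.3, 2.1)
  prior <- c(0.2, 0.5, 0.3)
  pg <- posteriorWeights(d, tr, "spherical",
                         priorGrid(alpha, tau2, prior, expand = FALSE))
  w_oracle <- posterior_oracle(d, tr, "spherical", tau2, alpha, prior)
  expect_equal(pg@post, w_oracle, tolerance = 1e-10)
})

test_that("posterior normalization is exact across random priors", {
  d <- toy_dataset(n = 15, seed = 53)
  set.seed(53)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    pr <- runif(k); pr <- pr / sum(pr)
    pg <- posteriorWeights(d, trendSpec(1L), "exponential",
      priorGrid(runif(k, 0.3, 3), runif(k, 0, 0.9), pr, expand = FALSE))
    expect_lt(abs(sum(pg@post) - 1), 1e-12)
  }
})

test_that("posterior weights are invariant to trend shifts", {
  d <- toy_dataset(n = 14, seed = 59)
  tr <- trendSpec(1L)
  grid <- priorGrid(c(0.7, 1.5), c(0.1, 0.5))
  p1 <- posteriorWeights(d, tr, "spherical", grid)@post
  d2 <- d
  d2@tvalue <- d@tvalue +
    as.numeric(designMatrix(tr, d@lat, d@lon) %*% c(4, -1, 2))
  p2 <- posteriorWeights(d2, tr, "spherical", grid)@post
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("parameter sampling reproduces its closed-form moments", {
  d <- toy_dataset(n = 30, seed = 61)
  tr <- trendSpec(1L)
  pg <- posteriorWeights(d, tr, "spherical", priorGrid(1.2, 0.4))
  nd <- 20000L
  par <- sampleParameters(pg, nd, seed = 101)
  np <- pg@n - pg@p
  S2 <- pg@cache[[1]]$S2
  m_true <- np * S2 / (np - 2)            # mean of scaled inverse chi-square
  se <- sd(par$sigma2) / sqrt(nd)
  expect_lt(abs(mean(par$sigma2) - m_true), 3 * se)
  # beta marginal mean is the GLS estimate
  for (j in 1:pg@p) {
    se_b <- sd(par$beta[, j]) / sqrt(nd)
    expect_lt(abs(mean(par$beta[, j]) - pg@cache[[1]]$betaHat[j]), 3 * se_b)
  }
})

test_that("multinomial frequencies converge to the posterior weights", {
  d <- toy_dataset(n = 20, seed = 67)
  pg <- posteriorWeights(d, trendSpec(1L), "spherical",
                         priorGrid(c(0.6, 1.2, 2.4), c(0.2, 0.5)))
  nd <- 20000L
  par <- sampleParameters(pg, nd, seed = 103)
  freq <- tabulate(par$index, length(pg@post)) / nd
  se <- sqrt(pg@post * (1 - pg@post) / nd)
  expect_true(all(abs(freq - pg@post) <= 3 * se + 1e-12))
})

test_that("identical seeds give bit-identical draw streams", {
  d <- toy_dataset(n = 15, seed = 71)
  pg <- posteriorWeights(d, trendSpec(1L), "spherical",
                         priorGrid(c(0.8, 1.6), c(0.1, 0.6)))
  tg <- cbind(c(1, 2), c(1, 2))
  a <- samplePredictive(d, trendSpec(1L), pg, tg, nDraws = 200, seed = 7)
  b <- samplePredictive(d, trendSpec(1L), pg, tg, nDraws = 200, seed = 7)
  expect_identical(a@draws, b@draws)
  expect_identical(a@paramIndex, b@paramIndex)
})

test_that("predictive draws hit the data exactly at zero nugget", {
  d <- toy_dataset(n = 10, seed = 73, nugget = 0)
  pg <- posteriorWeights(d, trendSpec(1L), "spherical", priorGrid(1.2, 0))
  dr <- samplePredictive(d, trendSpec(1L), pg, coords(d)[3, , drop = FALSE],
                         nDraws = 50, seed = 5)
  expect_equal(as.numeric(dr@draws), rep(tvalues(d)[3], 50), tolerance = 1e-6)
})

test_that("integrating the sill inflates the predictive variance", {
  set.seed(79)
  for (rep in 1:20) {
    d <- toy_dataset(n = sample(10:20, 1), seed = 900 + rep,
                     nugget = runif(1, 0.1, 0.6))
    tr <- trendSpec(1L)
    t2 <- runif(1, 0.1, 0.6); a <- runif(1, 0.6, 2)
    pg <- posteriorWeights(d, tr, "spherical", priorGrid(a, t2))
    tgt <- rbind(c(runif(1, 0, 3), runif(1, 0, 3)))
    dr <- samplePredictive(d, tr, pg, tgt, nDraws = 4000, seed = rep)
    S2 <- pg@cache[[1]]$S2
    plug <- ukPredict(d, variogramModel("spherical", S2, a, t2), tr,
                      tgt)@variance
    # predictive variance = E[sigma2] v_u >= S2 v_u, up to MC noise
    expect_gt(var(as.numeric(dr@draws)), plug * 0.85)
  }
})

test_that("credible intervals are equal-tailed empirical quantiles", {
  cd <- new("PredictiveDraws", draws = matrix(5, 200, 1), seed = 1L,
            paramIndex = rep(1L, 200))
  expect_equal(as.numeric(credibleInterval(cd)), c(5, 5))
  set.seed(83)
  zn <- new("PredictiveDraws", draws = matrix(rnorm(1e5), ncol = 1),
            seed = 1L, paramIndex = rep(1L, 1e5))
  ci <- credibleInterval(zn, 0.95)
  expect_equal(as.numeric(ci), c(-1.96, 1.96), tolerance = 0.03)
  un <- new("PredictiveDraws", draws = matrix(runif(1e5), ncol = 1),
            seed = 1L, paramIndex = rep(1L, 1e5))
  ci2 <- credibleInterval(un, 0.5)
  expect_equal(as.numeric(ci2), c(0.25, 0.75), tolerance = 0.01)
})

test_that("Bayesian LOOCV with a degenerate prior is plug-in LOOCV", {
  d <- toy_dataset(n = 25, seed = 89)
  tr <- trendSpec(1L)
  fit <- fitVariogramML(d, tr, "spherical", "REML", nStarts = 2L)
  pg <- priorGrid(fit@model@alpha, fit@model@tau2rel)
  b <- bayesLoocvRmspe(d, tr, "spherical", prior = pg)
  u <- loocvRmspe(d, model = fit@model, trend = tr)
  expect_equal(as.numeric(b), as.numeric(u), tolerance = 1e-8)
})

test_that("per-fold posterior refitting stays close to fixed weights", {
  d <- toy_dataset(n = 15, seed = 97)
  pr <- priorGrid(c(0.8, 1.6), c(0.2, 0.5))
  fixed <- as.numeric(bayesLoocvRmspe(d, family = "spherical", prior = pr))
  refit <- as.numeric(bayesLoocvRmspe(d, family = "spherical", prior = pr,
                                      refit = TRUE))
  expect_lt(abs(fixed - refit) / fixed, 0.2)
})
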