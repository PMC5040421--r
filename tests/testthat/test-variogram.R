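test_that("correlation families match their closed forms", {
  expect_equal(corrFunction("spherical", 0, 1), 1)
  expect_equal(corrFunction("spherical", 0.5, 1), 0.3125)
  expect_equal(corrFunction("spherical", 2, 1), 0)
  expect_equal(corrFunction("exponential", 1.3, 1.3), exp(-1))
  expect_equal(corrFunction("gaussian", 2, 1), exp(-4))
  u <- 0.4
  expect_equal(corrFunction("cubic", u, 1),
               1 - (7 * u^2 - 8.75 * u^3 + 3.5 * u^5 - 0.75 * u^7))
  expect_error(corrFunction("spherical", -1, 1), "negative")
})

test_that("semivariance has the nugget jump and attains the sill", {
  m <- variogramModel("spherical", sill = 2, range = 1, nugget = 0.25)
  expect_equal(semivariance(m, 0), 0)
  expect_equal(semivariance(m, 2), 2)            # beyond range: total sill
  expect_equal(semivariance(m, 1e-12), 0.5, tolerance = 1e-9)  # nugget jump
  # study-model parameters: sill attained exactly at the range
  m2 <- variogramModel("spherical", 0.7078, 1.1709, 0.43)
  expect_equal(semivariance(m2, 1.1709), 0.7078)
})

test_that("nugget can be supplied as an absolute variance", {
  m <- variogramModel("spherical", 0.7078, 1.1709, 0.43,
                      nugget.type = "absolute")
  expect_equal(m@tau2rel, 0.43 / 0.7078)
})

test_that("semivariance is non-decreasing for all families", {
  h <- seq(0, 4, length.out = 800)
  for (fam in c("exponential", "gaussian", "spherical", "cubic")) {
    m <- variogramModel(fam, sill = 1.4, range = 1.7, nugget = 0.2)
    expect_true(all(diff(semivariance(m, h)) >= -1e-12), info = fam)
  }
})

test_that("gamma(h) + C(h) = sill for h > 0 (conservation identity)", {
  h <- seq(0.01, 5, length.out = 300)
  for (fam in c("exponential", "gaussian", "spherical", "cubic")) {
    m <- variogramModel(fam, sill = 0.9, range = 1.1, nugget = 0.35)
    expect_equal(semivariance(m, h) + covariance(m, h), rep(0.9, length(h)),
                 tolerance = 1e-12, info = fam)
  }
})

test_that("every family yields a positive-definite covariance matrix", {
  set.seed(99)
  for (rep in 1:125) {
    n <- sample(5:25, 1)
    lat <- runif(n, 0, 4); lon <- runif(n, 0, 4)
    fam <- sample(c("exponential", "gaussian", "spherical", "cubic"), 1)
    m <- variogramModel(fam, sill = runif(1, 0.1, 3),
                        range = runif(1, 0.2, 5),
                        nugget = runif(1, 0, 0.9))
    S <- covarianceMatrix(m, lat, lon)
    expect_error(chol(S), NA)
  }
})

test_that("two-point empirical variogram equals the defining formula", {
  d <- geoDataset(c(0, 0), c(0, 1), c(10, 30), tvalue = c(2, 5))
  ev <- empiricalVariogram(d, trendSpec(0L), nbins = 1L, maxDist = 2)
  expect_equal(length(ev@lagCenters), 1L)
  expect_equal(ev@gammaHat, (5 - 2)^2 / 2)
  expect_equal(ev@pairCounts, 1L)
})

test_that("binned estimator matches brute-force pair enumeration", {
  d <- toy_dataset(n = 25, seed = 8)
  tr <- trendSpec(1L)
  md <- max(dist(coords(d))) / 2
  ev <- empiricalVariogram(d, tr, nbins = 13L, maxDist = md)
  bf <- brute_variogram(d, tr, 13L, md)
  expect_equal(ev@gammaHat, bf$gamma, tolerance = 1e-12)
  expect_equal(as.numeric(ev@pairCounts), bf$counts)
  expect_equal(ev@lagCenters, bf$centers)
})

test_that("pure-nugget fields give a flat empirical variogram", {
  # slope of gammaHat on lag should be indistinguishable from zero on
  # average over replicates
  slopes <- sapply(1:50, function(s) {
    d <- toy_dataset(n = 100, seed = 1000 + s, nugget = 0.999, sill = 1,
                     range_ = 0.5, beta = c(5, 0, 0))
    ev <- empiricalVariogram(d, trendSpec(1L))
    coef(lm(ev@gammaHat ~ ev@lagCenters))[2]
  })
  ci <- mean(slopes) + c(-3, 3) * sd(slopes) / sqrt(length(slopes))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("curve fitting recovers a noiseless spherical variogram", {
  truth <- variogramModel("spherical", sill = 0.8, range = 1.5, nugget = 0.3)
  h <- seq(0.1, 2.4, length.out = 12)
  ev <- new("EmpiricalVariogram", lagCenters = h,
            gammaHat = semivariance(truth, h),
            pairCounts = rep(50L, length(h)))
  for (w in c("OLS", "WLS")) {
    fit <- fitVariogram(ev, "spherical", w)
    expect_true(fit@converged)
    expect_equal(fit@model@sigma2, 0.8, tolerance = 1e-4)
    expect_equal(fit@model@alpha, 1.5, tolerance = 1e-4)
    expect_equal(fit@model@tau2rel, 0.3, tolerance = 1e-3)
  }
})

test_that("curve fit beats an exhaustive parameter lattice", {
  d <- toy_dataset(n = 60, seed = 21)
  ev <- empiricalVariogram(d, trendSpec(1L))
  fit <- fitVariogram(ev, "spherical", "OLS")
  # 30^3 lattice over the parameter box
  sills <- seq(0.05, 2.5, length.out = 30)
  ranges <- seq(0.05, max(ev@lagCenters) * 1.5, length.out = 30)
  nuggets <- seq(0, 0.95, length.out = 30)
  best_lattice <- Inf
  for (s in sills) for (a in ranges) {
    g0 <- semivariance(variogramModel("spherical", s, a, 0), ev@lagCenters)
    for (t2 in nuggets) {
      gm <- s * t2 + (1 - t2) * g0
      obj <- sum((ev@gammaHat - gm)^2)
      if (obj < best_lattice) best_lattice <- obj
    }
  }
  expect_lte(fit@objective, best_lattice + 1e-6)
})

test_that("curve fitting under moderate noise lands near the truth", {
  ests <- sapply(1:10, function(s) {
    d <- toy_dataset(n = 150, seed = 500 + s, sill = 0.7, range_ = 1.2,
                     nugget = 0.4, bbox = c(0, 4, 0, 4))
    f <- fitVariogram(empiricalVariogram(d, trendSpec(1L)), "spherical", "WLS")
    c(f@model@sigma2, f@model@alpha)
  })
  expect_lt(abs(median(ests[1, ]) - 0.7) / 0.7, 0.35)
  expect_lt(abs(median(ests[2, ]) - 1.2) / 1.2, 0.35)
})
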