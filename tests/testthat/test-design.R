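toy_model <- variogramModel("spherical", sill = 0.7, range = 1.2, nugget = 0.3)

test_that("MUKV over a single node equals the kriging variance there", {
  d <- toy_dataset(n = 12, seed = 101)
  g1 <- new("EvaluationGrid", lat = 1.5, lon = 1.5, spacing = 1)
  v <- ukPredict(d, toy_model, trendSpec(1L), cbind(1.5, 1.5))@variance
  expect_equal(mukv(coords(d), toy_model, trendSpec(1L), g1), v)
  expect_equal(mukv(coords(d), toy_model, trendSpec(1L), g1, stat = "sum"), v)
})

test_that("MUKV is zero when a zero-nugget design covers the grid", {
  d <- toy_dataset(n = 9, seed = 103)
  m0 <- variogramModel("spherical", 0.7, 1.2, 0)
  g <- new("EvaluationGrid", lat = d@lat[1:4], lon = d@lon[1:4], spacing = 1)
  expect_lt(mukv(coords(d), m0, trendSpec(1L), g), 1e-8)
})

test_that("mean and sum conventions differ exactly by the node count", {
  d <- toy_dataset(n = 10, seed = 105)
  g <- makeGrid(c(0, 3, 0, 3), 1)
  expect_equal(mukv(coords(d), toy_model, trendSpec(1L), g, "sum"),
               mukv(coords(d), toy_model, trendSpec(1L), g, "mean") *
                 nSites(g))
})

test_that("add-mode perturbation moves one site within the radius", {
  d0 <- initialDesign(toy_dataset(n = 8, seed = 107), "add", 3,
                      bbox = c(0, 3, 0, 3), seed = 1)
  set.seed(2)
  expect_identical(perturbDesign(d0, radius = 0)@freeLat, d0@freeLat)
  set.seed(3)
  d1 <- perturbDesign(d0, radius = 0.25)
  moved <- which(d1@freeLat != d0@freeLat | d1@freeLon != d0@freeLon)
  expect_length(moved, 1L)
  disp <- sqrt((d1@freeLat[moved] - d0@freeLat[moved])^2 +
               (d1@freeLon[moved] - d0@freeLon[moved])^2)
  expect_lte(disp, 0.25 + 1e-12)
  expect_identical(d1@fixedLat, d0@fixedLat)
})

test_that("delete-mode swap conserves cardinalities and the network", {
  net <- coords(toy_dataset(n = 10, seed = 109))
  d0 <- initialDesign(net, "delete", 4, seed = 1)
  set.seed(4)
  d1 <- perturbDesign(d0)
  expect_length(d1@freeLat, 4L)
  expect_length(d1@fixedLat, 6L)
  all0 <- sort(paste(c(d0@fixedLat, d0@freeLat), c(d0@fixedLon, d0@freeLon)))
  all1 <- sort(paste(c(d1@fixedLat, d1@freeLat), c(d1@fixedLon, d1@freeLon)))
  expect_identical(all0, all1)   # same network, different partition
})

test_that("displacement directions are uniform on the circle", {
  d0 <- initialDesign(cbind(0:3, 0:3), "add", 1,
                      bbox = c(-100, 100, -100, 100), seed = 1)
  set.seed(11)
  angles <- replicate(10000, {
    d1 <- perturbDesign(d0, radius = 0.5)
    atan2(d1@freeLon[1] - d0@freeLon[1], d1@freeLat[1] - d0@freeLat[1])
  })
  counts <- table(cut(angles, seq(-pi, pi, length.out = 9)))
  expect_gt(chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("acceptance rule is greedy at vanishing temperature", {
  set.seed(13)
  expect_true(ssaAccept(-0.1, 1e-12))
  expect_true(ssaAccept(0, 1e-12))
  expect_false(any(replicate(200, ssaAccept(0.01, 1e-12))))
})

test_that("SSA trace of the best objective is non-increasing", {
  d <- toy_dataset(n = 10, seed = 113)
  g <- makeGrid(c(0, 3, 0, 3), 0.75)
  for (mode in c("add", "delete")) {
    init <- initialDesign(d, mode, 3, seed = 5)
    r <- ssaOptimize(init, toy_model, trendSpec(1L), g,
                     ssaOptions(maxIter = 60, chainLength = 15, seed = 5))
    expect_true(all(diff(r$trace$best) <= 0))
    expect_equal(r$best@score, min(r$trace$best))
  }
})

test_that("SSA is deterministic given the seed", {
  d <- toy_dataset(n = 8, seed = 115)
  g <- makeGrid(c(0, 3, 0, 3), 1)
  init <- initialDesign(d, "add", 2, seed = 9)
  o <- ssaOptions(maxIter = 40, chainLength = 10, seed = 21)
  r1 <- ssaOptimize(init, toy_model, trendSpec(1L), g, o)
  r2 <- ssaOptimize(init, toy_model, trendSpec(1L), g, o)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best@freeLat, r2$best@freeLat)
})

test_that("exhaustive oracle boundary cases behave as defined", {
  net <- coords(toy_dataset(n = 6, seed = 117))
  g <- makeGrid(c(0, 3, 0, 3), 1)
  d0 <- exhaustiveDesign(net, 0L, toy_model, trendSpec(1L), g)
  expect_length(d0@freeLat, 0L)
  expect_equal(mukv(net, toy_model, trendSpec(1L), g), d0@score)
  expect_error(exhaustiveDesign(matrix(runif(60), 30), 15L, toy_model,
                                trendSpec(1L), g, cap = 1000), "cap")
})

test_that("exhaustive oracle matches an independent subset scan", {
  net <- coords(toy_dataset(n = 8, seed = 119))
  g <- makeGrid(c(0, 3, 0, 3), 1)
  d <- exhaustiveDesign(net, 2L, toy_model, trendSpec(1L), g)
  # double-entry: recompute every subset score through ukPredict directly
  subsets <- combn(8, 2)
  vals <- apply(subsets, 2, function(del) {
    keep <- net[-del, ]
    dummy <- geoDataset(keep[, 1], keep[, 2], rep(1, nrow(keep)))
    mean(ukPredict(dummy, toy_model, trendSpec(1L), g)@variance)
  })
  expect_equal(d@score, min(vals), tolerance = 1e-12)
  deleted <- sort(paste(d@freeLat, d@freeLon))
  bestdel <- subsets[, which.min(vals)]
  expect_identical(deleted, sort(paste(net[bestdel, 1], net[bestdel, 2])))
})

test_that("kmeans radius initializer returns a positive local scale", {
  net <- coords(toy_dataset(n = 40, seed = 121))
  r <- kmeansRadius(net, k = 6)
  expect_gt(r, 0)
  expect_lt(r, max(dist(net)))
})
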