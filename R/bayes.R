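# Bayesian universal kriging with a discrete prior on (relative nugget,
# range), a flat prior on the trend coefficients and the noninformative
# 1/sigma2 prior on the sill. The posterior over the discrete support is
# available in closed form; the sill's conditional posterior is scaled
# inverse chi-square with n - p degrees of freedom and scale S2; prediction
# is by composition sampling: draw covariance parameters from the discrete
# posterior, the sill from its conditional, then the target value from the
# Gaussian with the universal kriging mean and variance under the drawn
# parameters.

#' Discrete prior over (relative nugget, range)
#'
#' Builds a \linkS4class{PosteriorGrid} carrying the support and prior
#' weights; posterior weights are filled by \code{\link{posteriorWeights}}.
#'
#' @param alpha numeric vector of range support values (> 0).
#' @param tau2rel numeric vector of relative-nugget support values in
#'   [0, 1). The support is the product grid of \code{alpha} and
#'   \code{tau2rel} unless \code{expand = FALSE}, in which case the two
#'   vectors are taken as parallel coordinates.
#' @param prior prior probabilities (recycled/normalized); default uniform.
#' @param expand take the product grid (default TRUE).
#' @return a \linkS4class{PosteriorGrid} with empty posterior.
#' @export
priorGrid <- function(alpha, tau2rel, prior = NULL, expand = TRUE) {
  if (expand) {
    g <- expand.grid(tau2rel = tau2rel, alpha = alpha)
    tau2rel <- g$tau2rel; alpha <- g$alpha
  } else {
    k <- max(length(alpha), length(tau2rel))
    alpha <- rep_len(alpha, k); tau2rel <- rep_len(tau2rel, k)
  }
  k <- length(alpha)
  if (is.null(prior)) prior <- rep(1 / k, k)
  prior <- rep_len(prior, k); prior <- prior / sum(prior)
  new("PosteriorGrid", tau2rel = tau2rel, alpha = alpha, prior = prior,
      logPost = numeric(0), post = numeric(0), family = character(0),
      cache = list(), n = NA_integer_, p = NA_integer_)
}

#' Default discrete prior for a dataset
#'
#' Range support: \code{nAlpha} equally spaced values in (0, half the
#' maximum pairwise distance]; relative nugget support 0, 0.05, ..., 0.95;
#' uniform prior over the product grid.
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param nAlpha number of range support values (default 51).
#' @param tau2Step spacing of the relative-nugget support (default 0.05).
#' @return a \linkS4class{PosteriorGrid}.
#' @export
defaultPrior <- function(data, nAlpha = 51L, tau2Step = 0.05) {
  halfMax <- max(dist(coords(data))) / 2
  priorGrid(alpha = seq(halfMax / nAlpha, halfMax, length.out = nAlpha),
            tau2rel = seq(0, 0.95, by = tau2Step))
}

# full GLS statistics under unit-sill correlation at (tau2rel, alpha)
s2StatFull <- function(data, trend, family, tau2rel, alpha) {
  y <- data@tvalue
  F <- designMatrix(trend, data@lat, data@lon)
  n <- length(y); p <- ncol(F)
  if (n <= p) stop("need n > p")
  D <- as.matrix(dist(cbind(data@lat, data@lon)))
  V <- corrMatrix(family, D, alpha, tau2rel)
  st <- corrStats(V, F, y)
  list(S2 = st$Q / (n - p), betaHat = st$betaHat, logdetR = st$logdetV,
       logdetFVF = st$logdetFVF, cholFVF = st$cholFVF, n = n, p = p)
}

#' Generalized residual scale statistic S2
#'
#' S2 = (Y - F betaHat)' R^-1 (Y - F betaHat) / (n - p) with betaHat the
#' generalized-least-squares trend estimate under the unit-sill correlation
#' matrix R at (tau2rel, alpha). S2 is the scale of the sill's conditional
#' posterior.
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param trend a \linkS4class{TrendSpec}.
#' @param family variogram family.
#' @param tau2rel relative nugget in [0, 1).
#' @param alpha range (> 0).
#' @return scalar S2, with attribute "betaHat".
#' @export
s2Stat <- function(data, trend, family, tau2rel, alpha) {
  st <- s2StatFull(data, trend, family, tau2rel, alpha)
  out <- st$S2
  attr(out, "betaHat") <- st$betaHat
  out
}

#' Posterior weights over the discrete covariance support
#'
#' For each support point (tau2rel, alpha) the integrated likelihood (trend
#' flat, sill with the 1/sigma2 prior) gives the unnormalized log posterior
#' log prior - (1/2) log|R| - (1/2) log|F' R^-1 F| - ((n-p)/2) log S2,
#' normalized by log-sum-exp. Per-point sufficient statistics (S2, betaHat
#' and the Cholesky factor of F' R^-1 F) are cached for sampling.
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param trend a \linkS4class{TrendSpec}.
#' @param family variogram family.
#' @param prior a \linkS4class{PosteriorGrid} from \code{\link{priorGrid}}
#'   or \code{\link{defaultPrior}}.
#' @return the grid with \code{logPost}, \code{post} and \code{cache}
#'   filled.
#' @export
posteriorWeights <- function(data, trend = trendSpec(1L), family, prior) {
  k <- length(prior@tau2rel)
  lp <- rep(-Inf, k)
  cache <- vector("list", k)
  n <- p <- NA_integer_
  for (i in seq_len(k)) {
    st <- tryCatch(
      s2StatFull(data, trend, family, prior@tau2rel[i], prior@alpha[i]),
      error = function(e) NULL)
    if (is.null(st) || st$S2 <= 0) next
    n <- st$n; p <- st$p
    lp[i] <- log(prior@prior[i]) - st$logdetR / 2 - st$logdetFVF / 2 -
      (st$n - st$p) / 2 * log(st$S2)
    cache[[i]] <- list(S2 = st$S2, betaHat = st$betaHat,
                       cholFVF = st$cholFVF)
  }
  if (all(!is.finite(lp)))
    stop("all support points numerically singular")
  M <- max(lp[is.finite(lp)])
  w <- exp(lp - M); w[!is.finite(lp)] <- 0
  prior@logPost <- lp
  prior@post <- w / sum(w)
  prior@family <- family
  prior@cache <- cache
  prior@n <- as.integer(n); prior@p <- as.integer(p)
  validObject(prior)
  prior
}

#' Sample model parameters from the posterior
#'
#' (tau2rel, alpha) by multinomial sampling over the discrete posterior;
#' given the support point, sigma2 = (n - p) S2 / X with X ~ chi-square
#' (n - p); given sigma2, beta Gaussian at the GLS estimate with covariance
#' sigma2 (F' R^-1 F)^-1.
#'
#' @param pg a normalized \linkS4class{PosteriorGrid} (from
#'   \code{\link{posteriorWeights}}).
#' @param nDraws number of draws (>= 1).
#' @param seed integer RNG seed.
#' @return list with \code{index}, \code{tau2rel}, \code{alpha},
#'   \code{sigma2} (vectors of length nDraws) and \code{beta}
#'   (nDraws x p matrix).
#' @export
sampleParameters <- function(pg, nDraws, seed = 1L) {
  if (nDraws < 1L) stop("nDraws must be >= 1")
  if (!length(pg@post)) stop("posterior weights not computed; run posteriorWeights")
  set.seed(seed)
  idx <- sample.int(length(pg@post), nDraws, replace = TRUE, prob = pg@post)
  np <- pg@n - pg@p
  S2 <- vapply(idx, function(i) pg@cache[[i]]$S2, 0)
  sigma2 <- np * S2 / rchisq(nDraws, df = np)
  beta <- matrix(NA_real_, nDraws, pg@p)
  for (d in seq_len(nDraws)) {
    cc <- pg@cache[[idx[d]]]
    # chol(F'R^-1F) = UA; beta ~ N(betaHat, sigma2 (UA'UA)^-1)
    z <- rnorm(pg@p)
    beta[d, ] <- cc$betaHat + sqrt(sigma2[d]) * backsolve(cc$cholFVF, z)
  }
  list(index = idx, tau2rel = pg@tau2rel[idx], alpha = pg@alpha[idx],
       sigma2 = sigma2, beta = beta)
}

#' Sample from the posterior-predictive distribution
#'
#' Composition sampling: draw (tau2rel, alpha) from the discrete posterior
#' and sigma2 from its conditional; with those fixed, the predictive at each
#' target is Gaussian with the universal kriging mean and the universal
#' kriging variance under the drawn covariance (the mean does not depend on
#' the sill, and the variance scales linearly in it, so the kriging system
#' is solved once per support point, not per draw).
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param trend a \linkS4class{TrendSpec}.
#' @param pg a normalized \linkS4class{PosteriorGrid}.
#' @param targets prediction targets (grid, matrix or data.frame).
#' @param nDraws number of predictive draws.
#' @param seed integer RNG seed; identical seeds give identical draws.
#' @return a \linkS4class{PredictiveDraws} (nDraws x nTargets, transformed
#'   scale).
#' @export
samplePredictive <- function(data, trend = trendSpec(1L), pg, targets,
                             nDraws = 1000L, seed = 1L) {
  tg <- asTargets(targets)
  m <- nrow(tg)
  par <- sampleParameters(pg, nDraws, seed)   # seeds the stream
  used <- sort(unique(par$index))
  ukMean <- ukVarU <- matrix(NA_real_, length(pg@post), m)
  for (i in used) {
    mod <- variogramModel(pg@family, sill = 1, range = pg@alpha[i],
                          nugget = pg@tau2rel[i])
    kr <- ukPredict(data, mod, trend, tg)
    ukMean[i, ] <- kr@mean
    ukVarU[i, ] <- kr@variance      # unit-sill variance; scales with sigma2
  }
  z <- matrix(rnorm(nDraws * m), nDraws, m)
  draws <- ukMean[par$index, , drop = FALSE] +
    sqrt(pmax(par$sigma2 * ukVarU[par$index, , drop = FALSE], 0)) * z
  new("PredictiveDraws", draws = draws, seed = as.integer(seed),
      paramIndex = as.integer(par$index))
}

#' Equal-tailed credible intervals from predictive draws
#'
#' @param draws a \linkS4class{PredictiveDraws} (>= 100 draws advised).
#' @param level interval level (default 0.95).
#' @return nTargets x 2 matrix with columns low, high.
#' @export
credibleInterval <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  q <- apply(draws@draws, 2, quantile, probs = c(a, 1 - a), names = FALSE,
             type = 7)
  out <- t(q)
  colnames(out) <- c("low", "high")
  out
}

#' Leave-one-out RMSPE under Bayesian universal kriging
#'
#' Each site is predicted by the posterior-predictive mean from the
#' remaining n - 1 sites. Because the predictive mean under fixed
#' (tau2rel, alpha) is the universal kriging predictor and does not involve
#' the sill, the posterior-predictive mean is the posterior-weight average
#' of per-support-point leave-one-out kriging predictions — no Monte Carlo
#' is needed and the result is deterministic given the weights. By default
#' the posterior weights are computed once from the full dataset and held
#' fixed across folds; \code{refit = TRUE} recomputes them on every fold.
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param trend a \linkS4class{TrendSpec}.
#' @param family variogram family.
#' @param prior a \linkS4class{PosteriorGrid}; default
#'   \code{\link{defaultPrior}(data)}.
#' @param backtransform report errors on the raw mg/L scale when a Box-Cox
#'   lambda is attached.
#' @param refit recompute posterior weights per fold (slow).
#' @param weightFloor support points with posterior weight below this are
#'   skipped when averaging (their contribution is renormalized away).
#' @return the RMSPE (scalar), with attribute "predictions".
#' @export
bayesLoocvRmspe <- function(data, trend = trendSpec(1L), family = "spherical",
                            prior = NULL, backtransform = TRUE,
                            refit = FALSE, weightFloor = 1e-10) {
  if (is.null(prior)) prior <- defaultPrior(data)
  n <- nSites(data)
  if (!refit) {
    pg <- posteriorWeights(data, trend, family, prior)
    keep <- which(pg@post > weightFloor)
    w <- pg@post[keep] / sum(pg@post[keep])
    predT <- rep(0, n)
    for (j in seq_along(keep)) {
      i <- keep[j]
      mod <- variogramModel(family, sill = 1, range = pg@alpha[i],
                            nugget = pg@tau2rel[i])
      predT <- predT + w[j] * loocvPredictions(data, mod, trend)$pred
    }
  } else {
    predT <- vapply(seq_len(n), function(i) {
      di <- geoDataset(data@lat[-i], data@lon[-i], data@value[-i],
                       tvalue = data@tvalue[-i],
                       lambda = if (length(data@lambda)) data@lambda else NULL)
      pgi <- posteriorWeights(di, trend, family, prior)
      keep <- which(pgi@post > weightFloor)
      w <- pgi@post[keep] / sum(pgi@post[keep])
      pr <- 0
      for (j in seq_along(keep)) {
        kk <- keep[j]
        mod <- variogramModel(family, sill = 1, range = pgi@alpha[kk],
                              nugget = pgi@tau2rel[kk])
        pr <- pr + w[j] *
          ukPredict(di, mod, trend, cbind(data@lat[i], data@lon[i]))@mean
      }
      pr
    }, 0)
  }
  lam <- boxcoxLambda(data)
  if (backtransform && !is.na(lam)) {
    obs <- data@value; pred <- invBoxCox(predT, lam)
  } else {
    obs <- data@tvalue; pred <- predT
  }
  out <- sqrt(mean((pred - obs)^2))
  attr(out, "predictions") <- pred
  out
}

#' JSON-ready posterior report
#'
#' @param pg a normalized \linkS4class{PosteriorGrid}.
#' @return list with support, prior, posterior weights and the MAP point.
#' @export
posteriorReport <- function(pg) {
  i <- which.max(pg@post)
  list(tau2rel = pg@tau2rel, alpha = pg@alpha, prior = pg@prior,
       post = pg@post,
       map = list(tau2rel = pg@tau2rel[i], alpha = pg@alpha[i],
                  weight = pg@post[i]))
}
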