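#' Construct a variogram model
#'
#' @param family "exponential", "gaussian", "spherical" or "cubic".
#' @param sill total sill sigma2 (> 0).
#' @param range range alpha (> 0, degrees).
#' @param nugget nugget parameter; interpreted according to
#'   \code{nugget.type}.
#' @param nugget.type "relative" (default): \code{nugget} is the nugget
#'   fraction tau2rel of the total sill; "absolute": \code{nugget} is the
#'   nugget variance, converted to tau2rel = nugget / sill.
#' @return a \linkS4class{VariogramModel}.
#' @export
variogramModel <- function(family, sill, range, nugget = 0,
                           nugget.type = c("relative", "absolute")) {
  nugget.type <- match.arg(nugget.type)
  tau2rel <- if (nugget.type == "absolute") nugget / sill else nugget
  new("VariogramModel", family = family, sigma2 = sill, alpha = range,
      tau2rel = tau2rel)
}

#' Correlation function of a variogram family
#'
#' Unit-sill, nugget-free correlation rho(h; alpha):
#' exponential exp(-h/alpha); gaussian exp(-(h/alpha)^2); spherical
#' 1 - 1.5u + 0.5u^3 for u = h/alpha <= 1, 0 beyond; cubic
#' 1 - (7u^2 - 8.75u^3 + 3.5u^5 - 0.75u^7) for u <= 1, 0 beyond.
#'
#' @param family family name.
#' @param h distances (>= 0), vectorized.
#' @param alpha range (> 0).
#' @return correlations in [0, 1].
#' @export
corrFunction <- function(family, h, alpha) {
  if (any(h < 0)) stop("negative distance")
  if (alpha <= 0) stop("range must be positive")
  u <- h / alpha
  switch(family,
    exponential = exp(-u),
    gaussian = exp(-u^2),
    spherical = ifelse(u >= 1, 0, 1 - 1.5 * u + 0.5 * u^3),
    cubic = ifelse(u >= 1, 0,
                   1 - (7 * u^2 - 8.75 * u^3 + 3.5 * u^5 - 0.75 * u^7)),
    stop("unknown family: ", family))
}

setMethod("semivariance", "VariogramModel", function(model, h) {
  if (any(h < 0)) stop("negative distance")
  g <- model@sigma2 * (model@tau2rel +
         (1 - model@tau2rel) * (1 - corrFunction(model@family, h, model@alpha)))
  g[h == 0] <- 0
  g
})

#' Covariogram C(h) = sigma2 - gamma(h)
#'
#' C(0) = sigma2 and C(h) = sigma2 (1 - tau2rel) rho(h) for h > 0.
#'
#' @param model a \linkS4class{VariogramModel}.
#' @param h distances.
#' @return covariances.
#' @export
covariance <- function(model, h) {
  cv <- model@sigma2 * (1 - model@tau2rel) *
    corrFunction(model@family, h, model@alpha)
  cv[h == 0] <- model@sigma2
  cv
}

#' Covariance matrix over a set of locations
#'
#' Sigma = sigma2 ((1 - tau2rel) R_alpha + tau2rel I), symmetric positive
#' definite for distinct locations.
#'
#' @param model a \linkS4class{VariogramModel}.
#' @param lat,lon coordinates.
#' @return n x n covariance matrix.
#' @export
covarianceMatrix <- function(model, lat, lon) {
  D <- as.matrix(dist(cbind(lat, lon)))
  S <- model@sigma2 * (1 - model@tau2rel) *
    corrFunction(model@family, D, model@alpha)
  diag(S) <- model@sigma2
  S
}

# unit-sill correlation matrix (1 - tau2) R_alpha + tau2 I, used by the
# likelihood and the Bayesian machinery where sigma2 factors out
corrMatrix <- function(family, D, alpha, tau2rel) {
  R <- (1 - tau2rel) * corrFunction(family, D, alpha)
  diag(R) <- 1
  R
}

# OLS residuals of the trend; the working residuals the empirical variogram
# is computed on (true GLS residuals would need the unknown covariance)
trendResiduals <- function(data, trend) {
  F <- designMatrix(trend, data@lat, data@lon)
  qr.resid(qr(F), data@tvalue)
}

#' Empirical semivariogram on trend residuals
#'
#' Classical (Matheron) moment estimator on ordinary-least-squares residuals
#' of the trend: gammaHat(h_k) = (1 / 2 N(h_k)) sum over pairs in bin k of
#' (r_i - r_j)^2, with equally spaced bins up to a distance cutoff (default
#' half the maximum pairwise distance). Bins with no pairs are dropped.
#'
#' @param data a \linkS4class{GeoDataset} with n >= 2 (n >= 10 for anything
#'   statistically meaningful).
#' @param trend a \linkS4class{TrendSpec}; residuals are taken about its OLS
#'   fit.
#' @param nbins number of lag bins (default 13).
#' @param maxDist distance cutoff; default half the maximum pairwise
#'   distance.
#' @return an \linkS4class{EmpiricalVariogram}.
#' @export
empiricalVariogram <- function(data, trend = trendSpec(1L), nbins = 13L,
                               maxDist = NULL) {
  n <- nSites(data)
  if (n < 2L) stop("need at least 2 points")
  r <- trendResiduals(data, trend)
  D <- dist(cbind(data@lat, data@lon))
  if (is.null(maxDist)) maxDist <- max(D) / 2
  d <- as.numeric(D)
  sq <- as.numeric(dist(r))^2   # (r_i - r_j)^2 over the same pair ordering
  keep <- d <= maxDist & d > 0
  d <- d[keep]; sq <- sq[keep]
  if (!length(d)) stop("no pairs within maxDist")
  breaks <- seq(0, maxDist, length.out = nbins + 1L)
  bin <- pmin(findInterval(d, breaks, rightmost.closed = TRUE), nbins)
  cnt <- tabulate(bin, nbins)
  gh <- vapply(seq_len(nbins), function(k)
    if (cnt[k]) sum(sq[bin == k]) / (2 * cnt[k]) else NA_real_, 0)
  ctr <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  keep <- cnt > 0L
  new("EmpiricalVariogram", lagCenters = ctr[keep], gammaHat = gh[keep],
      pairCounts = as.integer(cnt[keep]))
}

# parameter transform used by all numeric fits: unconstrained <-> natural
vgmTheta <- function(sigma2, alpha, tau2rel)
  c(log(sigma2), log(alpha), qlogisN(tau2rel))
vgmFromTheta <- function(theta, family)
  variogramModel(family, sill = exp(theta[1]), range = exp(theta[2]),
                 nugget = plogisN(theta[3]))
qlogisN <- function(p) log(pmax(p, 1e-12) / pmax(1 - p, 1e-12))
plogisN <- function(x) 1 / (1 + exp(-x))

# documented multistart grid for curve and likelihood fits: fractions of the
# empirical sill / max lag spanning the (sill, range, nugget) box
vgmStarts <- function(sillScale, distScale) {
  list(c(sillScale, 0.50 * distScale, 0.05),
       c(sillScale, 0.25 * distScale, 0.30),
       c(0.5 * sillScale, 0.75 * distScale, 0.50),
       c(1.5 * sillScale, 0.40 * distScale, 0.15),
       c(sillScale, 0.10 * distScale, 0.70))
}

#' Fit a variogram model to an empirical variogram
#'
#' Least-squares curve fitting of the parametric semivariogram to the binned
#' estimates: OLS minimizes sum (gammaHat_k - gamma(h_k))^2; WLS minimizes
#' the Cressie-weighted sum N_k (gammaHat_k - gamma(h_k))^2 / gamma(h_k)^2.
#' Nelder-Mead on log/logit-transformed parameters from 5 documented starts;
#' among ties (objective within 1e-9) the smallest range wins.
#'
#' @param emp an \linkS4class{EmpiricalVariogram} with >= 4 bins.
#' @param family variogram family.
#' @param weighting "OLS" or "WLS".
#' @param errorOnFailure raise an error if no start converges (otherwise a
#'   flagged result is returned).
#' @return a \linkS4class{VariogramFit}.
#' @export
fitVariogram <- function(emp, family, weighting = c("OLS", "WLS"),
                         errorOnFailure = FALSE) {
  weighting <- match.arg(weighting)
  k <- length(emp@lagCenters)
  if (k < 4L) stop("need at least 4 non-empty bins")
  h <- emp@lagCenters; g <- emp@gammaHat; nk <- emp@pairCounts
  obj <- function(theta) {
    m <- vgmFromTheta(theta, family)
    gm <- semivariance(m, h)
    if (any(gm <= 0)) return(1e10)
    if (weighting == "OLS") sum((g - gm)^2) else sum(nk * (g - gm)^2 / gm^2)
  }
  best <- NULL
  for (s in vgmStarts(max(g), max(h))) {
    fit <- tryCatch(
      optim(vgmTheta(s[1], s[2], s[3]), obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         exp(fit$par[2]) < exp(best$par[2])))
      best <- fit
  }
  if (is.null(best)) {
    if (errorOnFailure) stop("variogram curve fit failed from all starts")
    return(new("VariogramFit",
               model = variogramModel(family, max(g), max(h), 0.5),
               method = weighting, objective = Inf, betaHat = numeric(0),
               converged = FALSE))
  }
  new("VariogramFit", model = vgmFromTheta(best$par, family),
      method = weighting, objective = best$value, betaHat = numeric(0),
      converged = best$convergence == 0L)
}
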