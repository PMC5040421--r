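# Universal kriging via the bordered semivariogram system, plus
# leave-one-out cross-validation.

# normalize a target specification to a 2-column (lat, lon) matrix
asTargets <- function(targets) {
  if (is(targets, "EvaluationGrid")) return(coords(targets))
  t <- as.matrix(targets)
  if (ncol(t) != 2L) stop("targets must have two columns (lat, lon)")
  colnames(t) <- c("lat", "lon")
  t
}

#' Universal kriging prediction
#'
#' Solves, for each target x0, the bordered (n+p) x (n+p) system
#' \deqn{[\Gamma, F; F', 0] [\lambda; l] = [\gamma_0; f_0]}
#' where Gamma holds pairwise semivariances among the data sites, F the trend
#' basis, gamma0 the semivariances to the target and f0 the basis at the
#' target. The predictor is lambda' Y and the kriging variance is
#' lambda' gamma0 + l' f0. Ordinary kriging is the constant-trend (p = 1)
#' special case. One factorization of the bordered matrix is reused for all
#' targets in the batch.
#'
#' @param data a \linkS4class{GeoDataset}; transformed values are predicted.
#' @param model a \linkS4class{VariogramModel}.
#' @param trend a \linkS4class{TrendSpec} (degree 0 for ordinary kriging).
#' @param targets an \linkS4class{EvaluationGrid}, or a 2-column matrix /
#'   data.frame of (lat, lon).
#' @param keepWeights retain the weight vectors and Lagrange multipliers.
#' @return a \linkS4class{KrigingResult}.
#' @export
ukPredict <- function(data, model, trend = trendSpec(1L), targets,
                      keepWeights = FALSE) {
  tg <- asTargets(targets)
  y <- data@tvalue
  n <- length(y)
  F <- designMatrix(trend, data@lat, data@lon)
  p <- ncol(F)
  if (n < p) stop("need at least p = ", p, " observations")
  D <- as.matrix(dist(cbind(data@lat, data@lon)))
  G <- semivariance(model, D)
  diag(G) <- 0
  B <- rbind(cbind(G, F), cbind(t(F), matrix(0, p, p)))
  # cross-distances data -> targets
  m <- nrow(tg)
  DX <- sqrt(outer(data@lat, tg[, 1], "-")^2 + outer(data@lon, tg[, 2], "-")^2)
  G0 <- matrix(semivariance(model, DX), n, m)
  G0[DX == 0] <- 0
  F0 <- t(designMatrix(trend, tg[, 1], tg[, 2]))
  RHS <- rbind(G0, F0)
  sol <- tryCatch(solve(B, RHS), error = function(e)
    stop("bordered kriging system singular: check for duplicate sites or ",
         "a rank-deficient trend basis (", conditionMessage(e), ")"))
  sol <- matrix(sol, n + p, m)
  lam <- sol[seq_len(n), , drop = FALSE]
  lag <- sol[n + seq_len(p), , drop = FALSE]
  pred <- as.numeric(crossprod(lam, y))
  v <- unname(colSums(lam * G0) + colSums(lag * F0))
  if (any(v < -1e-10))
    stop("kriging variance substantially negative (min ", min(v),
         "): numerical breakdown")
  # coincident targets give exact zeros up to roundoff; clamp those
  # silently, warn about anything larger in (-1e-10, -1e-13]
  if (any(v < -1e-13))
    warning(sum(v < -1e-13), " tiny negative kriging variance(s) clamped to 0")
  v[v < 0] <- 0
  new("KrigingResult", lat = tg[, 1], lon = tg[, 2], mean = pred,
      variance = v,
      weights = if (keepWeights) lam else matrix(0, 0, 0),
      lagrange = if (keepWeights) lag else matrix(0, 0, 0))
}

#' Leave-one-out kriging predictions under a fixed model
#'
#' With the covariance held fixed, the leave-one-out universal kriging
#' residual and variance at every site come in closed form from
#' H = Sigma^-1 - Sigma^-1 F (F' Sigma^-1 F)^-1 F' Sigma^-1 (the precision of
#' the GLS residuals): e_i = (H Y)_i / H_ii and sigma2_i = 1 / H_ii. This is
#' algebraically identical to deleting site i and solving the bordered
#' kriging system on the remaining n - 1 sites, at a fraction of the cost.
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param model a \linkS4class{VariogramModel}.
#' @param trend a \linkS4class{TrendSpec}.
#' @return list with \code{pred} and \code{variance}, one entry per site
#'   (on the transformed scale).
#' @export
loocvPredictions <- function(data, model, trend = trendSpec(1L)) {
  y <- data@tvalue
  F <- designMatrix(trend, data@lat, data@lon)
  S <- covarianceMatrix(model, data@lat, data@lon)
  Si <- tryCatch(chol2inv(chol(S)), error = function(e)
    stop("covariance matrix singular under the supplied model"))
  SiF <- Si %*% F
  H <- Si - SiF %*% solve(crossprod(F, SiF), t(SiF))
  hd <- diag(H)
  if (any(hd <= 0)) stop("degenerate leave-one-out system")
  e <- as.numeric(H %*% y) / hd
  list(pred = y - e, variance = 1 / hd)
}

#' Leave-one-out cross-validation RMSPE
#'
#' Each site is predicted from the remaining n - 1 by universal (or
#' ordinary) kriging and the root mean squared prediction error
#' sqrt(mean((Yhat_i - Y_i)^2)) is returned. By default the variogram
#' parameters are held fixed across folds (estimate once, cross-validate
#' with the model fixed); \code{refit = TRUE} re-estimates them on every
#' fold.
#'
#' When the dataset carries a Box-Cox exponent and
#' \code{backtransform = TRUE} (the default), predictions are mapped back to
#' the measurement scale (mg/L) before the error is computed; otherwise the
#' RMSPE is on the transformed scale.
#'
#' @param data a \linkS4class{GeoDataset} with n >= p + 2.
#' @param model a fixed \linkS4class{VariogramModel}; if NULL, fitted on the
#'   full dataset by \code{method}.
#' @param trend a \linkS4class{TrendSpec}.
#' @param family variogram family (used when \code{model} is NULL).
#' @param method "REML", "ML", "OLS" or "WLS" (used when \code{model} is
#'   NULL; OLS/WLS fit the empirical variogram).
#' @param backtransform report errors on the raw mg/L scale when a Box-Cox
#'   lambda is attached.
#' @param refit re-estimate the variogram on each fold (slow; ML/REML only).
#' @return the RMSPE (scalar), with attribute "predictions".
#' @export
loocvRmspe <- function(data, model = NULL, trend = trendSpec(1L),
                       family = "spherical",
                       method = c("REML", "ML", "OLS", "WLS"),
                       backtransform = TRUE, refit = FALSE) {
  method <- match.arg(method)
  n <- nSites(data)
  if (n < trendRank(trend) + 2L) stop("need n >= p + 2")
  if (is.null(model)) {
    model <- if (method %in% c("OLS", "WLS"))
      fitVariogram(empiricalVariogram(data, trend), family, method)@model
    else fitVariogramML(data, trend, family, method)@model
  }
  if (!refit) {
    predT <- loocvPredictions(data, model, trend)$pred
  } else {
    if (!method %in% c("REML", "ML"))
      stop("per-fold refitting is available for ML/REML only")
    predT <- vapply(seq_len(n), function(i) {
      di <- geoDataset(data@lat[-i], data@lon[-i], data@value[-i],
                       tvalue = data@tvalue[-i],
                       lambda = if (length(data@lambda)) data@lambda else NULL)
      fi <- fitVariogramML(di, trend, model@family, method, nStarts = 2L)
      ri <- tryCatch(
        ukPredict(di, fi@model, trend, cbind(data@lat[i], data@lon[i])),
        error = function(e) stop("fold for site ", data@ids[i], " failed: ",
                                 conditionMessage(e)))
      ri@mean
    }, 0)
  }
  lam <- boxcoxLambda(data)
  if (backtransform && !is.na(lam)) {
    obs <- data@value
    pred <- invBoxCox(predT, lam)
  } else {
    obs <- data@tvalue
    pred <- predT
  }
  out <- sqrt(mean((pred - obs)^2))
  attr(out, "predictions") <- pred
  out
}
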