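# Gaussian likelihood machinery for covariance-parameter estimation.
#
# The model is Y ~ N(F beta, sigma2 V) with V = (1 - tau2) R_alpha + tau2 I.
# beta is always profiled out by generalized least squares; sigma2 can be
# profiled in closed form, which reduces ML/REML fitting to a 2-d search
# over (alpha, tau2).

# Cholesky-based sufficient statistics under unit-sill correlation V.
# Returns logdetV, Q = r' V^-1 r (r the GLS residual), betaHat,
# logdetFVF = log|F' V^-1 F|, and the upper Cholesky factor of F'V^-1F.
corrStats <- function(V, F, y) {
  U <- chol(V)                              # V = U'U
  Fw <- backsolve(U, F, transpose = TRUE)   # U'^-1 F
  yw <- backsolve(U, y, transpose = TRUE)
  A <- crossprod(Fw)                        # F' V^-1 F
  UA <- chol(A)
  betaHat <- backsolve(UA, backsolve(UA, crossprod(Fw, yw), transpose = TRUE))
  rw <- yw - Fw %*% betaHat
  list(logdetV = 2 * sum(log(diag(U))), Q = sum(rw^2),
       betaHat = as.numeric(betaHat), logdetFVF = 2 * sum(log(diag(UA))),
       cholFVF = UA, U = U)
}

#' Gaussian negative log-likelihood of a variogram model
#'
#' Negative log-likelihood of Y ~ N(F beta, Sigma) with
#' Sigma = sigma2((1 - tau2rel) R_alpha + tau2rel I) and beta profiled out by
#' generalized least squares. With \code{restricted = TRUE} the restricted
#' (REML) criterion is returned: the likelihood of an orthonormal basis of
#' error contrasts, i.e. the ML value plus
#' (1/2) log|F' Sigma^-1 F| - (1/2) log|F'F| with the Gaussian constant taken
#' over (n - p) dimensions. All constants are included, so the REML value
#' equals the ML value of any orthonormal contrast basis exactly.
#'
#' @param data a \linkS4class{GeoDataset} (transformed values are used).
#' @param trend a \linkS4class{TrendSpec}.
#' @param model a \linkS4class{VariogramModel}.
#' @param restricted logical; REML criterion if TRUE.
#' @return the scalar negative log (restricted) likelihood.
#' @export
negLogLik <- function(data, trend, model, restricted = FALSE) {
  y <- data@tvalue
  n <- length(y)
  F <- designMatrix(trend, data@lat, data@lon)
  p <- ncol(F)
  D <- as.matrix(dist(cbind(data@lat, data@lon)))
  V <- corrMatrix(model@family, D, model@alpha, model@tau2rel)
  st <- tryCatch(corrStats(V, F, y), error = function(e)
    stop("covariance matrix singular at sigma2 = ", model@sigma2,
         ", alpha = ", model@alpha, ", tau2rel = ", model@tau2rel))
  s2 <- model@sigma2
  nll <- n / 2 * log(2 * pi) + n / 2 * log(s2) + st$logdetV / 2 +
    st$Q / (2 * s2)
  if (restricted) {
    ldFF <- 2 * sum(log(abs(diag(qr.R(qr(F))))))
    nll <- nll - p / 2 * log(2 * pi) - p / 2 * log(s2) +
      st$logdetFVF / 2 - ldFF / 2
  }
  nll
}

# profiled criterion over (alpha, tau2): sigma2hat = Q/n (ML) or Q/(n-p)
# (REML) substituted in closed form
profiledCriterion <- function(D, F, y, family, alpha, tau2rel, restricted) {
  n <- length(y); p <- ncol(F)
  V <- corrMatrix(family, D, alpha, tau2rel)
  st <- tryCatch(corrStats(V, F, y), error = function(e) NULL)
  if (is.null(st) || st$Q <= 0) return(NULL)
  if (restricted) {
    s2 <- st$Q / (n - p)
    ldFF <- 2 * sum(log(abs(diag(qr.R(qr(F))))))
    val <- (n - p) / 2 * log(2 * pi) + (n - p) / 2 * log(s2) +
      st$logdetV / 2 + st$logdetFVF / 2 - ldFF / 2 + (n - p) / 2
  } else {
    s2 <- st$Q / n
    val <- n / 2 * log(2 * pi) + n / 2 * log(s2) + st$logdetV / 2 + n / 2
  }
  list(value = val, sigma2 = s2, betaHat = st$betaHat)
}

#' Fit a variogram model by maximum or restricted maximum likelihood
#'
#' Numerical minimization of the (restricted) negative log-likelihood over
#' (log alpha, logit tau2rel) with the sill profiled out in closed form.
#' Nelder-Mead from a set of documented starting points spanning the range /
#' nugget box; the best optimum is returned. Deterministic: the starts are
#' fixed, no randomness is involved. Among ties the smallest range wins.
#'
#' @param data a \linkS4class{GeoDataset} with n > p.
#' @param trend a \linkS4class{TrendSpec} (default linear).
#' @param family variogram family.
#' @param method "REML" (default) or "ML".
#' @param nStarts number of starting points (1-5, default 5).
#' @return a \linkS4class{VariogramFit} with \code{betaHat} the GLS trend
#'   coefficients at the optimum and \code{objective} the attained negative
#'   log (restricted) likelihood.
#' @export
fitVariogramML <- function(data, trend = trendSpec(1L), family,
                           method = c("REML", "ML"), nStarts = 5L) {
  method <- match.arg(method)
  restricted <- method == "REML"
  y <- data@tvalue
  n <- length(y)
  F <- designMatrix(trend, data@lat, data@lon)
  if (n <= ncol(F)) stop("need n > p")
  D <- as.matrix(dist(cbind(data@lat, data@lon)))
  distScale <- max(D)
  obj <- function(par) {
    pc <- profiledCriterion(D, F, y, family, exp(par[1]), plogisN(par[2]),
                            restricted)
    if (is.null(pc)) 1e10 else pc$value
  }
  starts <- vgmStarts(1, distScale)[seq_len(max(1L, min(5L, nStarts)))]
  best <- NULL
  for (s in starts) {
    fit <- optim(c(log(s[2]), qlogisN(s[3])), obj, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         exp(fit$par[1]) < exp(best$par[1])))
      best <- fit
  }
  if (best$value >= 1e10) stop("likelihood fit failed from all starts")
  pc <- profiledCriterion(D, F, y, family, exp(best$par[1]),
                          plogisN(best$par[2]), restricted)
  model <- variogramModel(family, sill = pc$sigma2, range = exp(best$par[1]),
                          nugget = plogisN(best$par[2]))
  new("VariogramFit", model = model, method = method, objective = best$value,
      betaHat = pc$betaHat, converged = best$convergence == 0L)
}

#' Serialize a fit to a JSON-ready list
#'
#' @param fit a \linkS4class{VariogramFit}.
#' @return a plain list (family, method, parameters, objective, convergence)
#'   suitable for \code{jsonlite::toJSON}.
#' @export
fitReport <- function(fit) {
  list(family = fit@model@family, method = fit@method,
       sill = fit@model@sigma2, range = fit@model@alpha,
       nugget_rel = fit@model@tau2rel,
       beta = if (length(fit@betaHat)) fit@betaHat else NULL,
       objective = fit@objective, converged = fit@converged)
}
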