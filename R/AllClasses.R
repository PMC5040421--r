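#' @import methods
#' @importFrom stats dist optim optimize rnorm runif rchisq quantile qnorm
#'   var median complete.cases setNames kmeans
#' @importFrom utils read.csv write.csv combn head
NULL

#' Point-referenced concentration data
#'
#' Holds site coordinates (decimal degrees), the raw concentration values
#' (mg/L, strictly positive), and optionally a Box-Cox transformed copy used
#' for Gaussian modelling. The transformed values are what all variogram,
#' kriging and Bayesian machinery operates on; the raw values are kept so
#' predictions can be reported on the measurement scale.
#'
#' @slot ids character record labels.
#' @slot lat,lon numeric, decimal degrees (first coordinate is latitude).
#' @slot value numeric, concentration in mg/L, strictly positive.
#' @slot tvalue numeric, transformed value (equals \code{value} when no
#'   transformation has been applied).
#' @slot lambda numeric of length 0 or 1; the Box-Cox exponent applied to
#'   produce \code{tvalue} (length 0 when untransformed).
#' @exportClass GeoDataset
setClass("GeoDataset",
  representation(ids = "character", lat = "numeric", lon = "numeric",
                 value = "numeric", tvalue = "numeric", lambda = "numeric"))

setValidity("GeoDataset", function(object) {
  n <- length(object@lat)
  if (n < 1L) return("need at least one site")
  if (length(object@lon) != n || length(object@value) != n ||
      length(object@tvalue) != n || length(object@ids) != n)
    return("ids, lat, lon, value, tvalue must have equal length")
  if (!all(is.finite(object@lat)) || !all(is.finite(object@lon)))
    return("non-finite coordinates")
  if (any(!is.finite(object@value)) || any(object@value <= 0))
    return("concentration values must be finite and strictly positive")
  if (length(object@lambda) > 1L) return("lambda must have length 0 or 1")
  key <- paste(object@lat, object@lon)
  if (anyDuplicated(key))
    return("duplicate coordinates present; deduplicate or jitter on read")
  TRUE
})

#' Polynomial coordinate trend
#'
#' Specifies the mean surface as a polynomial in (lat, lon). Degree 0 is the
#' constant mean of ordinary kriging; degree 1 is the linear trend
#' beta1 + beta2*lat + beta3*lon of universal kriging with linear trend.
#' The first basis function is always the constant 1.
#'
#' @slot degree integer polynomial degree (0, 1 or 2).
#' @exportClass TrendSpec
setClass("TrendSpec", representation(degree = "integer"))

setValidity("TrendSpec", function(object) {
  if (length(object@degree) != 1L || is.na(object@degree) ||
      object@degree < 0L || object@degree > 2L)
    return("degree must be 0, 1 or 2")
  TRUE
})

#' Regular evaluation grid
#'
#' Lattice of unsampled locations over a bounding box, used as prediction
#' targets and as the averaging grid of the MUKV design objective.
#'
#' @slot lat,lon numeric node coordinates (decimal degrees).
#' @slot spacing numeric grid spacing in degrees.
#' @slot mask optional logical inclusion flags (length 0 when absent);
#'   excluded nodes are kept in the lattice but dropped by \code{coords}
#'   and \code{nSites}.
#' @exportClass EvaluationGrid
setClass("EvaluationGrid",
  representation(lat = "numeric", lon = "numeric", spacing = "numeric",
                 mask = "logical"),
  prototype(mask = logical(0)))

setValidity("EvaluationGrid", function(object) {
  if (length(object@lat) != length(object@lon)) return("lat/lon length mismatch")
  if (length(object@lat) < 1L) return("empty grid")
  if (anyDuplicated(paste(object@lat, object@lon))) return("duplicate nodes")
  if (length(object@spacing) != 1L || object@spacing <= 0) return("spacing must be > 0")
  if (length(object@mask) &&
      (length(object@mask) != length(object@lat) || !any(object@mask)))
    return("mask must match the node count and retain at least one node")
  TRUE
})

#' Parametric variogram / covariance model
#'
#' Parametrizes the covariance of the (transformed) field as
#' Sigma = sigma2 * ((1 - tau2rel) * R_alpha + tau2rel * I), i.e. total sill
#' sigma2, range alpha and *relative* nugget tau2rel (the nugget fraction of
#' the sill). The matching semivariogram is
#' gamma(h) = sigma2 * (tau2rel + (1 - tau2rel) * (1 - rho(h/alpha))) for
#' h > 0 and gamma(0) = 0.
#'
#' @slot family one of "exponential", "gaussian", "spherical", "cubic".
#' @slot sigma2 total sill (> 0), in variance units of the modelled scale.
#' @slot alpha range parameter, degrees (> 0).
#' @slot tau2rel relative nugget in [0, 1).
#' @exportClass VariogramModel
setClass("VariogramModel",
  representation(family = "character", sigma2 = "numeric",
                 alpha = "numeric", tau2rel = "numeric"))

setValidity("VariogramModel", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% c("exponential", "gaussian", "spherical", "cubic"))
    return("family must be one of exponential, gaussian, spherical, cubic")
  if (length(object@sigma2) != 1L || !is.finite(object@sigma2) || object@sigma2 <= 0)
    return("sigma2 (total sill) must be a positive number")
  if (length(object@alpha) != 1L || !is.finite(object@alpha) || object@alpha <= 0)
    return("alpha (range) must be a positive number")
  if (length(object@tau2rel) != 1L || !is.finite(object@tau2rel) ||
      object@tau2rel < 0 || object@tau2rel >= 1)
    return("tau2rel (relative nugget) must lie in [0, 1)")
  TRUE
})

#' Binned empirical semivariogram
#'
#' Classical (Matheron) moment estimator on trend residuals; bins with zero
#' pairs are dropped.
#'
#' @slot lagCenters numeric, strictly increasing bin centers (degrees).
#' @slot gammaHat numeric semivariance estimates.
#' @slot pairCounts integer pair counts per bin.
#' @exportClass EmpiricalVariogram
setClass("EmpiricalVariogram",
  representation(lagCenters = "numeric", gammaHat = "numeric",
                 pairCounts = "integer"))

setValidity("EmpiricalVariogram", function(object) {
  k <- length(object@lagCenters)
  if (length(object@gammaHat) != k || length(object@pairCounts) != k)
    return("slot length mismatch")
  if (k > 1L && any(diff(object@lagCenters) <= 0))
    return("lagCenters must be strictly increasing")
  if (any(object@pairCounts < 1L)) return("bins with zero pairs must be excluded")
  TRUE
})

#' Variogram fit result
#'
#' @slot model the fitted \linkS4class{VariogramModel}.
#' @slot method one of "ML", "REML", "OLS", "WLS".
#' @slot objective attained criterion value (negative log-likelihood for
#'   ML/REML, weighted residual sum of squares for OLS/WLS).
#' @slot betaHat generalized-least-squares trend coefficients (ML/REML only;
#'   length 0 otherwise).
#' @slot converged logical convergence flag.
#' @exportClass VariogramFit
setClass("VariogramFit",
  representation(model = "VariogramModel", method = "character",
                 objective = "numeric", betaHat = "numeric",
                 converged = "logical"))

setValidity("VariogramFit", function(object) {
  if (!object@method %in% c("ML", "REML", "OLS", "WLS")) return("unknown method")
  if (isTRUE(object@converged) && !is.finite(object@objective))
    return("objective must be finite when converged")
  TRUE
})

#' Kriging predictions
#'
#' Per-target universal (or ordinary) kriging predictor and kriging variance,
#' with the weight vectors and Lagrange multipliers optionally retained.
#'
#' @slot lat,lon target coordinates.
#' @slot mean predicted value per target, on the modelled scale.
#' @slot variance kriging variance per target (>= 0).
#' @slot weights n x m matrix of kriging weights (0 x 0 unless requested).
#' @slot lagrange p x m matrix of Lagrange multipliers (0 x 0 unless requested).
#' @exportClass KrigingResult
setClass("KrigingResult",
  representation(lat = "numeric", lon = "numeric", mean = "numeric",
                 variance = "numeric", weights = "matrix", lagrange = "matrix"))

setValidity("KrigingResult", function(object) {
  m <- length(object@lat)
  if (length(object@lon) != m || length(object@mean) != m ||
      length(object@variance) != m)
    return("slot length mismatch")
  if (any(object@variance < 0)) return("negative kriging variance")
  TRUE
})

#' Discrete posterior over (relative nugget, range)
#'
#' Support points of the discrete prior on (tau2rel, alpha) together with
#' prior and posterior weights and per-point sufficient statistics: the GLS
#' trend estimate, its unscaled covariance factor, and the scale statistic
#' S2 entering the scaled-inverse-chi-square conditional of the sill.
#'
#' @slot tau2rel,alpha parallel numeric vectors defining the support.
#' @slot prior prior probabilities (sum 1).
#' @slot logPost unnormalized log posterior per support point.
#' @slot post normalized posterior probabilities (sum 1).
#' @slot family correlation family the weights were computed under.
#' @slot cache list of per-point statistics (S2, betaHat, betaCovU) filled by
#'   \code{posteriorWeights}; empty before.
#' @slot n,p data size and trend rank the posterior was computed from.
#' @exportClass PosteriorGrid
setClass("PosteriorGrid",
  representation(tau2rel = "numeric", alpha = "numeric", prior = "numeric",
                 logPost = "numeric", post = "numeric", family = "character",
                 cache = "list", n = "integer", p = "integer"))

setValidity("PosteriorGrid", function(object) {
  k <- length(object@tau2rel)
  if (k < 1L) return("empty support")
  if (length(object@alpha) != k || length(object@prior) != k)
    return("support/prior length mismatch")
  if (any(object@prior < 0) || abs(sum(object@prior) - 1) > 1e-8)
    return("prior must be a probability vector")
  if (any(object@alpha <= 0)) return("alpha support must be positive")
  if (any(object@tau2rel < 0 | object@tau2rel >= 1))
    return("tau2rel support must lie in [0, 1)")
  if (length(object@post) == k && abs(sum(object@post) - 1) > 1e-8)
    return("posterior weights must sum to 1")
  TRUE
})

#' Posterior-predictive draws
#'
#' @slot draws nDraws x nTargets matrix of simulated values at the targets.
#' @slot seed integer seed the stream was generated from.
#' @slot paramIndex support-point index used for each draw.
#' @exportClass PredictiveDraws
setClass("PredictiveDraws",
  representation(draws = "matrix", seed = "integer", paramIndex = "integer"))

setValidity("PredictiveDraws", function(object) {
  if (!all(is.finite(object@draws))) return("non-finite draws")
  if (length(object@paramIndex) != nrow(object@draws))
    return("one support index per draw required")
  TRUE
})

#' Candidate monitoring-network design
#'
#' A design is a set of fixed locations (the part of the network that cannot
#' change) plus free locations subject to optimization. In "add" mode the
#' free locations are new sites placed anywhere in the bounding box; in
#' "delete" mode the free set is the subset of an existing network currently
#' marked for deletion (the retained network is fixed + not-deleted).
#'
#' @slot fixedLat,fixedLon coordinates that never move.
#' @slot freeLat,freeLon coordinates subject to perturbation (in delete mode,
#'   the currently deleted sites).
#' @slot mode "add" or "delete".
#' @slot bbox numeric(4): (latMin, latMax, lonMin, lonMax).
#' @slot score numeric of length 0 or 1: MUKV of the design if evaluated.
#' @exportClass SpatialDesign
setClass("SpatialDesign",
  representation(fixedLat = "numeric", fixedLon = "numeric",
                 freeLat = "numeric", freeLon = "numeric",
                 mode = "character", bbox = "numeric", score = "numeric"))

setValidity("SpatialDesign", function(object) {
  if (length(object@fixedLat) != length(object@fixedLon) ||
      length(object@freeLat) != length(object@freeLon))
    return("coordinate length mismatch")
  if (!object@mode %in% c("add", "delete")) return("mode must be add or delete")
  if (length(object@bbox) != 4L || object@bbox[1] >= object@bbox[2] ||
      object@bbox[3] >= object@bbox[4])
    return("bbox must be (latMin, latMax, lonMin, lonMax) with positive extent")
  allLat <- c(object@fixedLat, object@freeLat)
  allLon <- c(object@fixedLon, object@freeLon)
  tol <- 1e-9
  if (length(allLat) &&
      (any(allLat < object@bbox[1] - tol) || any(allLat > object@bbox[2] + tol) ||
       any(allLon < object@bbox[3] - tol) || any(allLon > object@bbox[4] + tol)))
    return("locations outside the bounding box")
  if (object@mode == "add" &&
      anyDuplicated(paste(allLat, allLon)))
    return("in add mode free locations must not coincide with fixed ones")
  if (length(object@score) > 1L) return("score must have length 0 or 1")
  TRUE
})

#' Spatial simulated annealing options
#'
#' @slot T0 initial temperature (> 0), or NA to calibrate from warm-up
#'   proposals so the initial worsening-acceptance rate is about 0.5.
#' @slot cooling multiplicative temperature factor in (0, 1).
#' @slot chainLength proposals per temperature stage.
#' @slot maxIter total proposal budget.
#' @slot perturbRadius displacement radius in degrees (add mode), shrunk by
#'   the cooling factor with temperature; NA to initialize via the k-means
#'   mean within-cluster diameter rule (k = 6).
#' @slot seed integer RNG seed.
#' @slot stopAfter stop after this many temperature stages without
#'   improvement of the best design.
#' @exportClass SSAOptions
setClass("SSAOptions",
  representation(T0 = "numeric", cooling = "numeric", chainLength = "integer",
                 maxIter = "integer", perturbRadius = "numeric",
                 seed = "integer", stopAfter = "integer"))

setValidity("SSAOptions", function(object) {
  if (!is.na(object@T0) && object@T0 <= 0) return("T0 must be > 0 (or NA)")
  if (object@cooling <= 0 || object@cooling >= 1) return("cooling must be in (0, 1)")
  if (object@chainLength < 1L || object@maxIter < 1L || object@stopAfter < 1L)
    return("chainLength, maxIter, stopAfter must be positive")
  if (!is.na(object@perturbRadius) && object@perturbRadius < 0)
    return("perturbRadius must be >= 0 (or NA)")
  TRUE
})
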