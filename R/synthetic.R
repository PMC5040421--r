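# Gaussian random field simulator emulating the study's statistical
# structure: n irregular sites in a bounding box, a linear coordinate trend,
# spherical covariance with nugget on the transformed scale, and an inverse
# Box-Cox back-transform to a positive, right-skewed concentration scale.

#' Simulation specification
#'
#' Defaults describe the reference study conditions: 370 irregularly spaced
#' sites in a box spanning latitudes 28-31.5 and longitudes 69.5-72 degrees,
#' a spherical covariance with total sill 0.7078, range 1.1709 and relative
#' nugget 0.43 on the transformed scale, a linear trend, and a Box-Cox
#' exponent of -0.028 linking the transformed scale to a sodium-like mg/L
#' scale.
#'
#' @param bbox numeric(4): latMin, latMax, lonMin, lonMax.
#' @param nSites number of sites.
#' @param beta trend coefficients on the transformed scale (constant, lat,
#'   lon for the default linear trend).
#' @param model a \linkS4class{VariogramModel} for the transformed field.
#' @param trend a \linkS4class{TrendSpec}.
#' @param lambdaBack Box-Cox exponent used to back-transform to the
#'   concentration scale.
#' @param layout "uniform" (default) scatters sites uniformly in the box;
#'   "clustered" places two sites per randomly chosen cell of a regular
#'   partition, mimicking paired sampling of administrative units.
#' @param seed integer RNG seed.
#' @return a list of settings for \code{\link{simulateGRF}}.
#' @export
simulationSpec <- function(bbox = c(28, 31.5, 69.5, 72),
                           nSites = 370L,
                           beta = c(12, -0.25, 0.01),
                           model = variogramModel("spherical", sill = 0.7078,
                                                  range = 1.1709,
                                                  nugget = 0.43),
                           trend = trendSpec(1L),
                           lambdaBack = -0.028,
                           layout = c("uniform", "clustered"),
                           seed = 1L) {
  stopifnot(length(bbox) == 4L, bbox[1] < bbox[2], bbox[3] < bbox[4],
            nSites >= 1L, length(beta) == trendRank(trend))
  list(bbox = bbox, nSites = as.integer(nSites), beta = beta, model = model,
       trend = trend, lambdaBack = lambdaBack, layout = match.arg(layout),
       seed = as.integer(seed))
}

# site layouts: uniform scatter, or two sites per sampled cell of a regular
# partition (pairs within a cell, cells spread over the region)
drawSites <- function(spec) {
  n <- spec$nSites; bbox <- spec$bbox
  if (is.null(spec$layout) || spec$layout == "uniform")
    return(cbind(runif(n, bbox[1], bbox[2]), runif(n, bbox[3], bbox[4])))
  nCells <- ceiling(n / 2)
  k <- ceiling(sqrt(nCells))
  cells <- sample.int(k * k, nCells)   # cell indices on a k x k partition
  ci <- (cells - 1) %/% k; cj <- (cells - 1) %% k
  dl <- (bbox[2] - bbox[1]) / k; dn <- (bbox[4] - bbox[3]) / k
  lat <- rep(bbox[1] + ci * dl, each = 2) + runif(2 * nCells, 0, dl)
  lon <- rep(bbox[3] + cj * dn, each = 2) + runif(2 * nCells, 0, dn)
  cbind(lat, lon)[seq_len(n), , drop = FALSE]
}

#' Simulate a Gaussian random field dataset
#'
#' Sites are drawn uniformly in the bounding box; the transformed field is
#' Y = F beta + L' z with L the Cholesky factor of the model covariance and
#' z standard normal; concentration-scale values are obtained by inverse
#' Box-Cox with \code{lambdaBack}. Both scales are stored, so the result
#' behaves exactly like a dataset read from file and then transformed.
#' Identical seeds give identical datasets.
#'
#' @param spec a list from \code{\link{simulationSpec}}.
#' @return a \linkS4class{GeoDataset} with \code{tvalue} the simulated
#'   Gaussian field and \code{value} its positive back-transform.
#' @export
simulateGRF <- function(spec = simulationSpec()) {
  set.seed(spec$seed)
  xy <- drawSites(spec)
  lat <- xy[, 1]; lon <- xy[, 2]
  F <- designMatrix(spec$trend, lat, lon)
  mu <- as.numeric(F %*% spec$beta)
  S <- covarianceMatrix(spec$model, lat, lon)
  L <- tryCatch(chol(S), error = function(e) {
    chol(S + diag(1e-10 * spec$model@sigma2, nrow(S)))   # jittered retry
  })
  yt <- mu + as.numeric(crossprod(L, rnorm(spec$nSites)))
  value <- invBoxCox(yt, spec$lambdaBack)
  geoDataset(lat, lon, value, tvalue = yt, lambda = spec$lambdaBack)
}

#' Regular evaluation grid over a bounding box
#'
#' Lattice at the given spacing, always including the bounding-box corners
#' (the last row/column is appended when the extent is not a multiple of the
#' spacing).
#'
#' @param bbox numeric(4): latMin, latMax, lonMin, lonMax.
#' @param spacing grid spacing in degrees (> 0).
#' @param mask optional predicate \code{function(lat, lon)} returning
#'   logical inclusion flags for the nodes (vectorized); masked-out nodes
#'   stay in the lattice but are ignored by \code{coords} and
#'   \code{nSites}.
#' @return an \linkS4class{EvaluationGrid}.
#' @export
makeGrid <- function(bbox = c(28, 31.5, 69.5, 72), spacing = 0.1,
                     mask = NULL) {
  stopifnot(length(bbox) == 4L, spacing > 0)
  axis <- function(lo, hi) {
    s <- seq(lo, hi, by = spacing)
    if (hi - s[length(s)] > 1e-9) s <- c(s, hi)
    s
  }
  if (spacing > max(bbox[2] - bbox[1], bbox[4] - bbox[3]))
    warning("spacing exceeds the bounding-box extent; corner-only grid")
  g <- expand.grid(lat = axis(bbox[1], bbox[2]), lon = axis(bbox[3], bbox[4]))
  flags <- if (is.null(mask)) logical(0) else as.logical(mask(g$lat, g$lon))
  new("EvaluationGrid", lat = g$lat, lon = g$lon, spacing = spacing,
      mask = flags)
}
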