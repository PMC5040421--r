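#' @title Accessors
#' @description Small accessor generics shared by the spatial containers.
#' @param x an object.
#' @param ... further arguments.
#' @return `nSites` the number of locations; `coords` a two-column matrix
#'   (lat, lon); `values`/`tvalues` the raw and transformed observation
#'   vectors; `boxcoxLambda` the Box-Cox exponent (NA when untransformed).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("tvalues", function(x) standardGeneric("tvalues"))

#' @rdname accessors
#' @export
setGeneric("boxcoxLambda", function(x) standardGeneric("boxcoxLambda"))

#' Semivariance of a variogram model
#'
#' gamma(0) = 0 and, for h > 0,
#' gamma(h) = sigma2 (tau2rel + (1 - tau2rel)(1 - rho(h / alpha))); the nugget
#' appears as a jump at the origin and gamma tends to the total sill sigma2
#' (reaching it exactly at h >= alpha for the spherical and cubic families).
#'
#' @param model a \linkS4class{VariogramModel}.
#' @param h numeric vector of distances (>= 0).
#' @return numeric vector of semivariances.
#' @export
setGeneric("semivariance", function(model, h) standardGeneric("semivariance"))

#' Trend design matrix
#'
#' Evaluates the polynomial coordinate basis at a set of locations. The first
#' column is always the constant 1; degree 1 adds lat and lon; degree 2 adds
#' lat^2, lat*lon, lon^2.
#'
#' @param trend a \linkS4class{TrendSpec}.
#' @param lat,lon numeric coordinate vectors.
#' @return n x p design matrix.
#' @export
setGeneric("designMatrix", function(trend, lat, lon) standardGeneric("designMatrix"))

setMethod("nSites", "GeoDataset", function(x) length(x@lat))
setMethod("nSites", "EvaluationGrid", function(x)
  if (length(x@mask)) sum(x@mask) else length(x@lat))
setMethod("nSites", "SpatialDesign",
          function(x) length(x@fixedLat) + length(x@freeLat))

setMethod("coords", "GeoDataset", function(x, ...)
  cbind(lat = x@lat, lon = x@lon))
setMethod("coords", "EvaluationGrid", function(x, ...) {
  out <- cbind(lat = x@lat, lon = x@lon)
  if (length(x@mask)) out[x@mask, , drop = FALSE] else out
})
setMethod("coords", "SpatialDesign", function(x, ...)
  cbind(lat = c(x@fixedLat, x@freeLat), lon = c(x@fixedLon, x@freeLon)))

setMethod("values", "GeoDataset", function(x) x@value)
setMethod("tvalues", "GeoDataset", function(x) x@tvalue)
setMethod("boxcoxLambda", "GeoDataset", function(x)
  if (length(x@lambda)) x@lambda else NA_real_)

setMethod("show", "GeoDataset", function(object) {
  cat("GeoDataset with", nSites(object), "sites\n")
  cat("  lat range:", sprintf("[%.4f, %.4f]", min(object@lat), max(object@lat)),
      " lon range:", sprintf("[%.4f, %.4f]\n", min(object@lon), max(object@lon)))
  cat("  value (mg/L):", sprintf("median %.3g, range [%.3g, %.3g]\n",
      median(object@value), min(object@value), max(object@value)))
  if (length(object@lambda))
    cat("  Box-Cox transformed, lambda =", format(object@lambda), "\n")
  invisible(object)
})

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf("VariogramModel: %s, total sill %.6g, range %.6g, relative nugget %.6g\n",
              object@family, object@sigma2, object@alpha, object@tau2rel))
  invisible(object)
})

setMethod("show", "VariogramFit", function(object) {
  cat(sprintf("VariogramFit (%s, %s): objective %.6g, %s\n",
              object@model@family, object@method, object@objective,
              if (isTRUE(object@converged)) "converged" else "NOT converged"))
  show(object@model)
  if (length(object@betaHat))
    cat("  trend coefficients:", paste(format(object@betaHat, digits = 5),
                                       collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "EmpiricalVariogram", function(object) {
  cat("EmpiricalVariogram with", length(object@lagCenters), "bins, lags",
      sprintf("[%.4g, %.4g]\n", min(object@lagCenters), max(object@lagCenters)))
  invisible(object)
})

setMethod("show", "KrigingResult", function(object) {
  cat("KrigingResult at", length(object@lat), "targets;",
      sprintf("variance range [%.4g, %.4g]\n",
              min(object@variance), max(object@variance)))
  invisible(object)
})

setMethod("show", "PosteriorGrid", function(object) {
  k <- length(object@tau2rel)
  cat("PosteriorGrid:", k, "support points over (tau2rel, alpha)\n")
  if (length(object@post) == k) {
    i <- which.max(object@post)
    cat(sprintf("  MAP: tau2rel = %.4g, alpha = %.4g (weight %.4g)\n",
                object@tau2rel[i], object@alpha[i], object@post[i]))
  } else cat("  posterior weights not yet computed\n")
  invisible(object)
})

setMethod("show", "SpatialDesign", function(object) {
  cat(sprintf("SpatialDesign (%s mode): %d fixed + %d free sites%s\n",
              object@mode, length(object@fixedLat), length(object@freeLat),
              if (length(object@score))
                sprintf(", MUKV %.6g", object@score) else ""))
  invisible(object)
})

setMethod("show", "EvaluationGrid", function(object) {
  cat("EvaluationGrid:", nSites(object), "nodes at spacing",
      object@spacing, "degrees\n")
  invisible(object)
})
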