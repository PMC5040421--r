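#' Construct a GeoDataset
#'
#' @param lat,lon numeric coordinates in decimal degrees; latitude is the
#'   first coordinate throughout the package.
#' @param value strictly positive concentrations (mg/L).
#' @param ids optional record labels (defaults to row numbers).
#' @param tvalue optional transformed values; defaults to \code{value}.
#' @param lambda Box-Cox exponent that produced \code{tvalue}, or NULL.
#' @param jitterDuplicates if TRUE, duplicated coordinates are jittered by
#'   1e-6 degrees with a warning instead of raising an error (duplicate sites
#'   make kriging matrices singular).
#' @return a validated \linkS4class{GeoDataset}.
#' @export
geoDataset <- function(lat, lon, value, ids = NULL, tvalue = NULL,
                       lambda = NULL, jitterDuplicates = FALSE) {
  lat <- as.numeric(lat); lon <- as.numeric(lon); value <- as.numeric(value)
  if (is.null(ids)) ids <- as.character(seq_along(lat))
  key <- paste(lat, lon)
  if (anyDuplicated(key)) {
    if (!jitterDuplicates)
      stop("duplicate coordinates at rows ",
           paste(which(duplicated(key)), collapse = ", "),
           "; set jitterDuplicates = TRUE to displace them by 1e-6 degrees")
    dup <- duplicated(key)
    warning(sum(dup), " duplicated coordinate(s) jittered by 1e-6 degrees")
    while (anyDuplicated(paste(lat, lon))) {
      dup <- duplicated(paste(lat, lon))
      lat[dup] <- lat[dup] + 1e-6
      lon[dup] <- lon[dup] + 1e-6
    }
  }
  if (is.null(tvalue)) tvalue <- value
  new("GeoDataset", ids = as.character(ids), lat = lat, lon = lon,
      value = value, tvalue = as.numeric(tvalue),
      lambda = if (is.null(lambda)) numeric(0) else as.numeric(lambda))
}

#' Construct a polynomial trend specification
#'
#' @param degree 0 (constant mean: ordinary kriging), 1 (linear trend:
#'   universal kriging with linear trend, the default) or 2 (quadratic).
#' @return a \linkS4class{TrendSpec}.
#' @export
trendSpec <- function(degree = 1L) new("TrendSpec", degree = as.integer(degree))

setMethod("designMatrix", "TrendSpec", function(trend, lat, lon) {
  stopifnot(length(lat) == length(lon))
  F <- cbind(rep(1, length(lat)))
  if (trend@degree >= 1L) F <- cbind(F, lat, lon)
  if (trend@degree >= 2L) F <- cbind(F, lat^2, lat * lon, lon^2)
  colnames(F) <- c("1", "lat", "lon", "lat2", "latlon", "lon2")[seq_len(ncol(F))]
  F
})

#' Number of trend basis functions
#' @param trend a \linkS4class{TrendSpec}.
#' @return integer p.
#' @export
trendRank <- function(trend) {
  c(1L, 3L, 6L)[trend@degree + 1L]
}

#' Box-Cox power transformation
#'
#' Forward transform (y^lambda - 1)/lambda for lambda != 0 and log(y) at
#' lambda = 0; \code{invBoxCox} is the exact inverse. The transform is used to
#' bring right-skewed concentration data close to Gaussian before variogram
#' modelling and kriging.
#'
#' @param y strictly positive values.
#' @param lambda transformation exponent.
#' @return transformed values.
#' @export
boxCox <- function(y, lambda) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("Box-Cox transform requires finite, strictly positive values")
  if (lambda == 0) log(y) else expm1(lambda * log(y)) / lambda
}

#' @rdname boxCox
#' @param z transformed values; must satisfy 1 + lambda*z > 0 when
#'   lambda != 0.
#' @export
invBoxCox <- function(z, lambda) {
  if (lambda == 0) return(exp(z))
  u <- 1 + lambda * z
  if (any(u <= 0))
    stop("inverse Box-Cox undefined: 1 + lambda*z must be positive")
  exp(log(u) / lambda)
}

#' Estimate the Box-Cox exponent by profile likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood under an i.i.d. normal
#' working model,
#' l(lambda) = -n/2 log(sigma2hat(lambda)) + (lambda - 1) sum(log y),
#' by golden-section search over a bracket (default [-2, 2], tolerance 1e-4).
#' By default the working-model mean is a constant; supplying a design
#' matrix \code{F} profiles the mean over a regression on it instead, which
#' matters when a strong spatial trend would otherwise masquerade as
#' marginal skewness.
#'
#' @param y strictly positive values, n >= 10.
#' @param F optional n x p design matrix for the working-model mean (e.g.
#'   \code{designMatrix(trendSpec(1L), lat, lon)}); NULL for a constant.
#' @param bracket numeric(2) search interval for lambda.
#' @param tol search tolerance.
#' @return the maximizing lambda.
#' @export
fitBoxCoxLambda <- function(y, F = NULL, bracket = c(-2, 2), tol = 1e-4) {
  if (length(y) < 10L) stop("need at least 10 values to estimate lambda")
  if (any(!is.finite(y)) || any(y <= 0)) stop("values must be positive")
  if (var(y) == 0) stop("constant input: lambda is unidentifiable")
  n <- length(y); slog <- sum(log(y))
  qrF <- if (is.null(F)) NULL else qr(F)
  prof <- function(lambda) {
    z <- boxCox(y, lambda)
    r <- if (is.null(qrF)) z - mean(z) else qr.resid(qrF, z)
    s2 <- sum(r^2) / n
    -n / 2 * log(s2) + (lambda - 1) * slog
  }
  optimize(prof, interval = bracket, maximum = TRUE, tol = tol)$maximum
}

#' Attach a Box-Cox transformation to a dataset
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param lambda exponent; if NULL it is estimated by
#'   \code{\link{fitBoxCoxLambda}}.
#' @param trend optional \linkS4class{TrendSpec}; when estimating lambda,
#'   profile the working-model mean over this coordinate basis instead of a
#'   constant.
#' @return the dataset with \code{tvalue} and \code{lambda} filled.
#' @export
transformDataset <- function(data, lambda = NULL, trend = NULL) {
  if (is.null(lambda))
    lambda <- fitBoxCoxLambda(data@value,
      F = if (is.null(trend)) NULL
          else designMatrix(trend, data@lat, data@lon))
  data@tvalue <- boxCox(data@value, lambda)
  data@lambda <- lambda
  validObject(data)
  data
}

#' Read point-referenced concentration data from CSV
#'
#' @param path CSV file with a header row.
#' @param columns named character vector mapping the roles lat, lon, value to
#'   column names; default \code{c(lat = "lat", lon = "long", value = "Na")}.
#' @param jitterDuplicates passed to \code{\link{geoDataset}}.
#' @param dropMissing drop rows with missing fields (with a message) rather
#'   than failing.
#' @return a \linkS4class{GeoDataset} (untransformed).
#' @export
readDataset <- function(path, columns = c(lat = "lat", lon = "long", value = "Na"),
                        jitterDuplicates = FALSE, dropMissing = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(all(c("lat", "lon", "value") %in% names(columns)))
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(columns[c("lat", "lon", "value")]), names(df))
  if (length(missing))
    stop("column(s) not present in ", path, ": ", paste(missing, collapse = ", "))
  lat <- suppressWarnings(as.numeric(df[[columns[["lat"]]]]))
  lon <- suppressWarnings(as.numeric(df[[columns[["lon"]]]]))
  val <- suppressWarnings(as.numeric(df[[columns[["value"]]]]))
  ok <- complete.cases(lat, lon, val)
  if (!all(ok)) {
    if (!dropMissing)
      stop("missing or non-numeric fields at row(s) ",
           paste(which(!ok), collapse = ", "))
    message(sum(!ok), " row(s) with missing fields dropped")
    lat <- lat[ok]; lon <- lon[ok]; val <- val[ok]
  }
  bad <- which(val <= 0)
  if (length(bad))
    stop("non-positive concentration at row ", paste(bad, collapse = ", "))
  message("read ", length(val), " records from ", path)
  geoDataset(lat, lon, val, jitterDuplicates = jitterDuplicates)
}

#' Write a dataset back to CSV
#'
#' Inverse of \code{\link{readDataset}} up to column order; round-trips all
#' fields at full precision.
#'
#' @param data a \linkS4class{GeoDataset}.
#' @param path output file.
#' @param columns column names for lat, lon, value.
#' @export
writeDataset <- function(data, path,
                         columns = c(lat = "lat", lon = "long", value = "Na")) {
  df <- data.frame(a = data@lat, b = data@lon, c = data@value)
  names(df) <- unname(columns[c("lat", "lon", "value")])
  write.csv(format(df, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write predictions to CSV
#'
#' Emits lat, lon, pred, pred_var, ci_low, ci_high at full precision.
#'
#' @param result a \linkS4class{KrigingResult} (or anything with lat, lon,
#'   mean, variance slots).
#' @param path output file.
#' @param ci optional 2 x m or m x 2 matrix / data.frame of interval bounds;
#'   defaults to the Gaussian 95 percent interval from the kriging variance.
#' @param level interval level for the Gaussian default.
#' @export
writePredictions <- function(result, path, ci = NULL, level = 0.95) {
  m <- length(result@lat)
  if (is.null(ci)) {
    z <- qnorm(1 - (1 - level) / 2)
    ci <- cbind(result@mean - z * sqrt(result@variance),
                result@mean + z * sqrt(result@variance))
  } else {
    ci <- as.matrix(ci)
    if (nrow(ci) != m) ci <- t(ci)
  }
  df <- data.frame(lat = result@lat, lon = result@lon, pred = result@mean,
                   pred_var = result@variance, ci_low = ci[, 1], ci_high = ci[, 2])
  write.csv(format(df, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
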