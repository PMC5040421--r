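# Monitoring-network design: the mean-universal-kriging-variance objective
# and spatial simulated annealing over add/delete moves.

# sites actually scored by the objective: in add mode all of them, in delete
# mode the retained network (fixed slots; free holds the deleted sites)
scoredCoords <- function(design) {
  if (design@mode == "add")
    cbind(lat = c(design@fixedLat, design@freeLat),
          lon = c(design@fixedLon, design@freeLon))
  else
    cbind(lat = design@fixedLat, lon = design@fixedLon)
}

#' Initial monitoring-network design
#'
#' Add mode: \code{k} new free locations drawn uniformly in the bounding box
#' are appended to the existing (fixed) network. Delete mode: \code{k}
#' network sites chosen at random are marked for deletion (the free set);
#' the retained sites stay fixed and the optimizer swaps deletion
#' candidates.
#'
#' @param network 2-column (lat, lon) matrix or \linkS4class{GeoDataset}:
#'   the existing monitoring network.
#' @param mode "add" or "delete".
#' @param k number of sites to add or delete.
#' @param bbox numeric(4) (latMin, latMax, lonMin, lonMax); defaults to the
#'   network's bounding box.
#' @param seed integer RNG seed for the random initialization.
#' @return a \linkS4class{SpatialDesign}.
#' @export
initialDesign <- function(network, mode = c("add", "delete"), k,
                          bbox = NULL, seed = 1L) {
  mode <- match.arg(mode)
  xy <- if (is(network, "GeoDataset")) coords(network) else as.matrix(network)
  if (is.null(bbox)) bbox <- c(range(xy[, 1]), range(xy[, 2]))
  set.seed(seed)
  if (mode == "add") {
    new("SpatialDesign", fixedLat = xy[, 1], fixedLon = xy[, 2],
        freeLat = runif(k, bbox[1], bbox[2]),
        freeLon = runif(k, bbox[3], bbox[4]),
        mode = "add", bbox = bbox, score = numeric(0))
  } else {
    if (k >= nrow(xy)) stop("cannot delete the whole network")
    del <- sample.int(nrow(xy), k)
    new("SpatialDesign", fixedLat = xy[-del, 1], fixedLon = xy[-del, 2],
        freeLat = xy[del, 1], freeLon = xy[del, 2],
        mode = "delete", bbox = bbox, score = numeric(0))
  }
}

#' Mean universal kriging variance of a design
#'
#' The design objective: the universal (or, with a constant trend, ordinary)
#' kriging variance is computed at every node of the evaluation grid from
#' the design's scored locations, and its arithmetic mean (or sum, see
#' \code{stat}) is returned. Smaller is better.
#'
#' @param design a \linkS4class{SpatialDesign}, or a 2-column (lat, lon)
#'   matrix of monitoring locations.
#' @param model a \linkS4class{VariogramModel}.
#' @param trend a \linkS4class{TrendSpec} (degree 0 gives the ordinary
#'   kriging variance).
#' @param grid an \linkS4class{EvaluationGrid} (or 2-column matrix).
#' @param stat "mean" (default) or "sum" of the per-node variances.
#' @return scalar objective value.
#' @export
mukv <- function(design, model, trend = trendSpec(1L), grid,
                 stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  xy <- if (is(design, "SpatialDesign")) scoredCoords(design)
        else as.matrix(design)
  if (nrow(xy) < trendRank(trend)) stop("design smaller than the trend rank")
  dummy <- geoDataset(xy[, 1], xy[, 2], rep(1, nrow(xy)))
  v <- ukPredict(dummy, model, trend, grid)@variance
  if (stat == "mean") mean(v) else sum(v)
}

#' Perturbation radius from k-means clustering
#'
#' Initializes the displacement neighborhood as the mean within-cluster
#' diameter of a k-means clustering (k = 6 by default) of the network: a
#' data-driven scale for "local" moves.
#'
#' @param network 2-column (lat, lon) matrix or \linkS4class{GeoDataset}.
#' @param k number of clusters.
#' @return scalar radius in degrees.
#' @export
kmeansRadius <- function(network, k = 6L) {
  xy <- if (is(network, "GeoDataset")) coords(network) else as.matrix(network)
  if (nrow(xy) <= k) return(max(dist(xy)))
  cl <- kmeans(xy, centers = k, nstart = 5L)
  diams <- vapply(seq_len(k), function(j) {
    pts <- xy[cl$cluster == j, , drop = FALSE]
    if (nrow(pts) < 2L) 0 else max(dist(pts))
  }, 0)
  mean(diams)
}

#' Randomly perturb a design
#'
#' Add mode: one uniformly chosen free location is displaced uniformly
#' within a disc of the given radius and clipped to the bounding box (radius
#' 0 is a null move). Delete mode: the deletion set is changed by swapping
#' one deleted site with one retained site; cardinalities are preserved.
#' Uses the current RNG stream (seed at the caller).
#'
#' @param design a \linkS4class{SpatialDesign} with a non-empty free set.
#' @param radius displacement radius in degrees (add mode).
#' @return the perturbed design (score cleared).
#' @export
perturbDesign <- function(design, radius = 0.1) {
  if (!length(design@freeLat)) stop("free set is empty")
  if (design@mode == "add") {
    i <- sample.int(length(design@freeLat), 1L)
    others <- paste(c(design@fixedLat, design@freeLat[-i]),
                    c(design@fixedLon, design@freeLon[-i]))
    # clipping to the box can land exactly on an existing site; such a
    # collision would make the kriging matrix singular, so redraw
    for (try in 1:10) {
      r <- radius * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      newLat <- min(max(design@freeLat[i] + r * cos(th),
                        design@bbox[1]), design@bbox[2])
      newLon <- min(max(design@freeLon[i] + r * sin(th),
                        design@bbox[3]), design@bbox[4])
      if (!(paste(newLat, newLon) %in% others)) {
        design@freeLat[i] <- newLat
        design@freeLon[i] <- newLon
        break
      }
    }
  } else {
    i <- sample.int(length(design@freeLat), 1L)   # deleted site to retain
    j <- sample.int(length(design@fixedLat), 1L)  # retained site to delete
    tmpLat <- design@freeLat[i]; tmpLon <- design@freeLon[i]
    design@freeLat[i] <- design@fixedLat[j]
    design@freeLon[i] <- design@fixedLon[j]
    design@fixedLat[j] <- tmpLat
    design@fixedLon[j] <- tmpLon
  }
  design@score <- numeric(0)
  design
}

#' Metropolis acceptance rule of simulated annealing
#'
#' Improvements (delta <= 0) are always accepted; worsenings with
#' probability exp(-delta / temperature). Consumes one uniform deviate only
#' when delta > 0.
#'
#' @param delta objective change (proposal minus current).
#' @param temperature current temperature (> 0).
#' @return logical: accept the proposal.
#' @export
ssaAccept <- function(delta, temperature) {
  if (delta <= 0) return(TRUE)
  runif(1) < exp(-delta / temperature)
}

#' Simulated annealing options
#'
#' @param T0 initial temperature; NA (default) calibrates it from 100
#'   warm-up proposals so that the initial worsening-acceptance rate is
#'   about 0.5.
#' @param cooling multiplicative temperature (and radius) decay per stage.
#' @param chainLength proposals per temperature stage.
#' @param maxIter total proposal budget.
#' @param perturbRadius add-mode displacement radius in degrees; NA
#'   (default) uses \code{\link{kmeansRadius}} of the network.
#' @param seed integer RNG seed.
#' @param stopAfter stop after this many stages without improvement.
#' @return an \linkS4class{SSAOptions}.
#' @export
ssaOptions <- function(T0 = NA_real_, cooling = 0.9, chainLength = 50L,
                       maxIter = 2000L, perturbRadius = NA_real_, seed = 1L,
                       stopAfter = 10L) {
  new("SSAOptions", T0 = T0, cooling = cooling,
      chainLength = as.integer(chainLength), maxIter = as.integer(maxIter),
      perturbRadius = perturbRadius, seed = as.integer(seed),
      stopAfter = as.integer(stopAfter))
}

#' Optimize a monitoring network by spatial simulated annealing
#'
#' Annealing loop over add/delete moves: a perturbation is proposed, its
#' MUKV change against the current design is computed, improvements are
#' always accepted and worsenings with probability exp(-delta / T); the
#' temperature is multiplied by the cooling factor every
#' \code{chainLength} proposals (the add-mode displacement radius shrinks
#' with it), and the best design seen is stored and returned together with
#' the full trace. Deterministic given \code{opts@seed}.
#'
#' @param initial a \linkS4class{SpatialDesign} (see
#'   \code{\link{initialDesign}}).
#' @param model a \linkS4class{VariogramModel}.
#' @param trend a \linkS4class{TrendSpec}.
#' @param grid an \linkS4class{EvaluationGrid}.
#' @param opts an \linkS4class{SSAOptions}.
#' @param stat passed to \code{\link{mukv}}.
#' @return list with \code{best} (a scored \linkS4class{SpatialDesign}) and
#'   \code{trace} (data.frame: iter, temperature, current, best, accepted).
#' @export
ssaOptimize <- function(initial, model, trend = trendSpec(1L), grid,
                        opts = ssaOptions(), stat = "mean") {
  set.seed(opts@seed)
  radius <- opts@perturbRadius
  if (is.na(radius)) radius <- kmeansRadius(coords(initial))
  score <- function(d) mukv(d, model, trend, grid, stat)
  current <- initial
  curVal <- score(current)
  T <- opts@T0
  if (is.na(T)) {
    # warm-up: median positive delta gives ~50% initial worsening acceptance
    deltas <- replicate(100, {
      s <- score(perturbDesign(current, radius))
      s - curVal
    })
    pos <- deltas[deltas > 0]
    T <- if (length(pos)) median(pos) / log(2) else
      max(abs(deltas), curVal * 1e-6, .Machine$double.eps)
  }
  best <- current; bestVal <- curVal
  trace <- data.frame(iter = integer(0), temperature = numeric(0),
                      current = numeric(0), best = numeric(0),
                      accepted = logical(0))
  stale <- 0L
  iter <- 0L
  while (iter < opts@maxIter && stale < opts@stopAfter) {
    improvedThisStage <- FALSE
    for (s in seq_len(opts@chainLength)) {
      iter <- iter + 1L
      prop <- perturbDesign(current, radius)
      propVal <- score(prop)
      acc <- ssaAccept(propVal - curVal, T)
      if (acc) { current <- prop; curVal <- propVal }
      if (curVal < bestVal - 1e-15) {
        best <- current; bestVal <- curVal; improvedThisStage <- TRUE
      }
      trace <- rbind(trace, data.frame(iter = iter, temperature = T,
                                       current = curVal, best = bestVal,
                                       accepted = acc))
      if (iter >= opts@maxIter) break
    }
    stale <- if (improvedThisStage) 0L else stale + 1L
    T <- T * opts@cooling
    radius <- radius * opts@cooling
  }
  best@score <- bestVal
  list(best = best, trace = trace)
}

#' Exhaustive deletion oracle
#'
#' Enumerates every way of deleting \code{kDelete} sites from the network
#' and returns the MUKV-minimal retained design. Intended as a ground-truth
#' check for \code{\link{ssaOptimize}} on small problems; guarded against
#' combinatorial explosion.
#'
#' @param network 2-column (lat, lon) matrix or \linkS4class{GeoDataset}.
#' @param kDelete number of sites to delete (0 returns the network itself).
#' @param model a \linkS4class{VariogramModel}.
#' @param trend a \linkS4class{TrendSpec}.
#' @param grid an \linkS4class{EvaluationGrid}.
#' @param stat passed to \code{\link{mukv}}.
#' @param cap maximum number of subsets enumerated (default 1e5).
#' @return a scored \linkS4class{SpatialDesign} in delete mode.
#' @export
exhaustiveDesign <- function(network, kDelete, model, trend = trendSpec(1L),
                             grid, stat = "mean", cap = 1e5) {
  xy <- if (is(network, "GeoDataset")) coords(network) else as.matrix(network)
  m <- nrow(xy)
  bbox <- c(range(xy[, 1]), range(xy[, 2]))
  if (kDelete == 0L) {
    d <- new("SpatialDesign", fixedLat = xy[, 1], fixedLon = xy[, 2],
             freeLat = numeric(0), freeLon = numeric(0), mode = "delete",
             bbox = bbox, score = numeric(0))
    d@score <- mukv(d, model, trend, grid, stat)
    return(d)
  }
  if (choose(m, kDelete) > cap)
    stop("C(", m, ", ", kDelete, ") exceeds the enumeration cap")
  subsets <- combn(m, kDelete)
  vals <- apply(subsets, 2, function(del)
    mukv(xy[-del, , drop = FALSE], model, trend, grid, stat))
  bestDel <- subsets[, which.min(vals)]
  d <- new("SpatialDesign", fixedLat = xy[-bestDel, 1],
           fixedLon = xy[-bestDel, 2], freeLat = xy[bestDel, 1],
           freeLon = xy[bestDel, 2], mode = "delete", bbox = bbox,
           score = min(vals))
  d
}

#' Write a design to CSV
#'
#' Emits lat, lon, status with status in fixed/added/deleted/retained.
#'
#' @param design a \linkS4class{SpatialDesign}.
#' @param path output file.
#' @export
writeDesign <- function(design, path) {
  if (design@mode == "add") {
    df <- data.frame(lat = c(design@fixedLat, design@freeLat),
                     lon = c(design@fixedLon, design@freeLon),
                     status = c(rep("fixed", length(design@fixedLat)),
                                rep("added", length(design@freeLat))))
  } else {
    df <- data.frame(lat = c(design@fixedLat, design@freeLat),
                     lon = c(design@fixedLon, design@freeLon),
                     status = c(rep("retained", length(design@fixedLat)),
                                rep("deleted", length(design@freeLat))))
  }
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
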