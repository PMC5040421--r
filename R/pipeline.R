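# Orchestration: the two study workflows as single calls.
# runCompare(): transform, fit every family x method, cross-validate
#   universal and Bayesian universal kriging, pick the winner, grid it.
# runDesign(): baseline MUKV and simulated-annealing add/delete designs for
#   ordinary and universal kriging variance.

#' Run configuration
#'
#' Flat list of settings shared by \code{\link{runCompare}} and
#' \code{\link{runDesign}}. Either \code{input} (a CSV path) or \code{sim}
#' (a \code{\link{simulationSpec}}) must be provided.
#'
#' @param input path to a CSV of observations, or NULL.
#' @param sim a \code{\link{simulationSpec}} list, or NULL.
#' @param columns column map for \code{\link{readDataset}}.
#' @param lambda Box-Cox exponent; NULL estimates it by profile likelihood.
#' @param trendDegree trend polynomial degree for universal kriging.
#' @param families variogram families to fit.
#' @param methods estimation methods to fit.
#' @param bayesFamilies families to cross-validate under Bayesian universal
#'   kriging.
#' @param nAlpha,tau2Step discrete-prior settings (see
#'   \code{\link{defaultPrior}}).
#' @param gridSpacing evaluation-grid spacing in degrees.
#' @param backtransform report RMSPE on the mg/L scale.
#' @param addCounts,deleteCounts site counts for the design workflow.
#' @param ssa an \linkS4class{SSAOptions} for the design workflow.
#' @param outDir output directory for report artifacts, or NULL to skip
#'   writing.
#' @param seed master seed; all stage seeds derive from it.
#' @return a config list.
#' @export
runConfig <- function(input = NULL, sim = NULL,
                      columns = c(lat = "lat", lon = "long", value = "Na"),
                      lambda = NULL, trendDegree = 1L,
                      families = c("exponential", "gaussian", "spherical", "cubic"),
                      methods = c("ML", "REML", "OLS", "WLS"),
                      bayesFamilies = c("exponential", "spherical"),
                      nAlpha = 21L, tau2Step = 0.1,
                      gridSpacing = 0.25, backtransform = TRUE,
                      addCounts = integer(0), deleteCounts = integer(0),
                      ssa = ssaOptions(), outDir = NULL, seed = 1L) {
  if (is.null(input) && is.null(sim))
    stop("provide either an input CSV path or a simulation spec")
  if (!length(families) || !length(methods))
    stop("need at least one family and one method")
  list(input = input, sim = sim, columns = columns, lambda = lambda,
       trendDegree = as.integer(trendDegree), families = families,
       methods = methods, bayesFamilies = bayesFamilies,
       nAlpha = as.integer(nAlpha), tau2Step = tau2Step,
       gridSpacing = gridSpacing, backtransform = backtransform,
       addCounts = as.integer(addCounts),
       deleteCounts = as.integer(deleteCounts), ssa = ssa, outDir = outDir,
       seed = as.integer(seed))
}

loadData <- function(config) {
  data <- if (!is.null(config$input))
    readDataset(config$input, config$columns)
  else simulateGRF(config$sim)
  if (is.na(boxcoxLambda(data)) || !is.null(config$lambda))
    data <- transformDataset(data, config$lambda)
  data
}

#' Model-comparison workflow
#'
#' Fits every requested (family x method) combination, computes the
#' leave-one-out RMSPE of universal kriging under each fit and of Bayesian
#' universal kriging for the requested families, flags the minimum, and (if
#' an output directory is set) writes the RMSPE matrix, fit reports, and
#' prediction / variance grids of the winning model.
#'
#' @param config from \code{\link{runConfig}}.
#' @return list with elements \code{data}, \code{lambda}, \code{fits}
#'   (nested by family/method), \code{rmspe} (family x method matrix),
#'   \code{bayesRmspe} (named by family), \code{best} (description of the
#'   minimum-RMSPE cell) and \code{failures}.
#' @export
runCompare <- function(config) {
  data <- loadData(config)
  trend <- trendSpec(config$trendDegree)
  fams <- config$families; meths <- config$methods
  rmspe <- matrix(NA_real_, length(fams), length(meths),
                  dimnames = list(fams, meths))
  fits <- list(); failures <- character(0)
  emp <- empiricalVariogram(data, trend)
  for (f in fams) for (m in meths) {
    res <- tryCatch({
      fit <- if (m %in% c("OLS", "WLS")) fitVariogram(emp, f, m)
             else fitVariogramML(data, trend, f, m)
      cv <- loocvRmspe(data, model = fit@model, trend = trend,
                       backtransform = config$backtransform)
      list(fit = fit, cv = as.numeric(cv))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(f, "/", m, ": ", conditionMessage(res)))
      next
    }
    fits[[f]][[m]] <- res$fit
    rmspe[f, m] <- res$cv
  }
  if (all(is.na(rmspe))) stop("every fit failed: ",
                              paste(failures, collapse = "; "))
  bayesRmspe <- setNames(rep(NA_real_, length(config$bayesFamilies)),
                         config$bayesFamilies)
  for (f in config$bayesFamilies) {
    res <- tryCatch(
      bayesLoocvRmspe(data, trend, f,
                      prior = defaultPrior(data, config$nAlpha,
                                           config$tau2Step),
                      backtransform = config$backtransform),
      error = function(e) e)
    if (inherits(res, "error"))
      failures <- c(failures, paste0("BUK/", f, ": ", conditionMessage(res)))
    else bayesRmspe[f] <- as.numeric(res)
  }
  # flag the overall minimum across UK cells and BUK entries
  cand <- setNames(as.numeric(rmspe), outer(fams, meths, paste, sep = "/"))
  if (length(bayesRmspe))
    cand <- c(cand, setNames(as.numeric(bayesRmspe),
                             paste0("BUK/", names(bayesRmspe))))
  best <- names(cand)[which.min(cand)]
  out <- list(lambda = boxcoxLambda(data), rmspe = rmspe,
              bayesRmspe = bayesRmspe, best = best,
              fits = fits, failures = failures, data = data)
  if (!is.null(config$outDir)) writeCompareArtifacts(out, config, trend)
  out
}

writeCompareArtifacts <- function(out, config, trend) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$rmspe, file.path(config$outDir, "rmspe_matrix.csv"))
  report <- list(
    seed = config$seed, lambda = out$lambda, best = out$best,
    rmspe = as.list(as.data.frame(out$rmspe)),
    bayes_rmspe = as.list(out$bayesRmspe),
    fits = lapply(out$fits, function(byMethod) lapply(byMethod, fitReport)),
    failures = out$failures)
  jsonlite::write_json(report, file.path(config$outDir, "compare_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # grid the winning plug-in model (BUK winner falls back to best UK cell)
  ukCells <- which(!is.na(out$rmspe), arr.ind = TRUE)
  if (nrow(ukCells)) {
    i <- ukCells[which.min(out$rmspe[ukCells]), ]
    fit <- out$fits[[rownames(out$rmspe)[i[1]]]][[colnames(out$rmspe)[i[2]]]]
    bbox <- c(range(out$data@lat), range(out$data@lon))
    grid <- makeGrid(bbox, config$gridSpacing)
    kr <- ukPredict(out$data, fit@model, trend, grid)
    lam <- boxcoxLambda(out$data)
    if (config$backtransform && !is.na(lam)) kr@mean <- invBoxCox(kr@mean, lam)
    writePredictions(kr, file.path(config$outDir, "prediction_grid.csv"))
  }
  invisible(NULL)
}

#' Design-optimization workflow
#'
#' Evaluates the baseline MUKV of the monitoring network under ordinary and
#' universal kriging variance, then runs spatial simulated annealing for
#' each requested add/delete count and predictor, writing designs and
#' traces when an output directory is set.
#'
#' @param config from \code{\link{runConfig}}; \code{addCounts} /
#'   \code{deleteCounts} select the tasks.
#' @param model a fitted \linkS4class{VariogramModel} used for both
#'   predictors; if NULL, a spherical REML model is fitted separately for
#'   each predictor under its own trend (constant for OK, the configured
#'   polynomial for UK), since the trend absorbs part of the sill during
#'   estimation.
#' @param data optional \linkS4class{GeoDataset}; loaded from the config if
#'   NULL.
#' @return list with \code{baseline} (named MUKV for OK and UK) and
#'   \code{runs}: one entry per task with the count, predictor, best design
#'   and its MUKV, and the annealing trace.
#' @export
runDesign <- function(config, model = NULL, data = NULL) {
  if (is.null(data)) data <- loadData(config)
  trends <- list(OK = trendSpec(0L), UK = trendSpec(config$trendDegree))
  models <- lapply(trends, function(tr) {
    if (!is.null(model)) model
    else fitVariogramML(data, tr, "spherical", "REML")@model
  })
  bbox <- c(range(data@lat), range(data@lon))
  grid <- makeGrid(bbox, config$gridSpacing)
  baseline <- vapply(names(trends), function(pr)
    mukv(coords(data), models[[pr]], trends[[pr]], grid), 0)
  runs <- list()
  taskSeed <- config$seed
  for (pred in names(trends)) {
    for (k in config$deleteCounts) {
      taskSeed <- taskSeed + 1L
      init <- initialDesign(data, "delete", k, bbox, seed = taskSeed)
      opts <- config$ssa; opts@seed <- taskSeed
      r <- ssaOptimize(init, models[[pred]], trends[[pred]], grid, opts)
      runs[[paste0(pred, "_delete_", k)]] <-
        list(predictor = pred, task = "delete", k = k,
             mukv = r$best@score, design = r$best, trace = r$trace)
    }
    for (k in config$addCounts) {
      taskSeed <- taskSeed + 1L
      init <- initialDesign(data, "add", k, bbox, seed = taskSeed)
      opts <- config$ssa; opts@seed <- taskSeed
      r <- ssaOptimize(init, models[[pred]], trends[[pred]], grid, opts)
      runs[[paste0(pred, "_add_", k)]] <-
        list(predictor = pred, task = "add", k = k,
             mukv = r$best@score, design = r$best, trace = r$trace)
    }
  }
  out <- list(baseline = baseline, runs = runs, models = models)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(runs)) {
      writeDesign(runs[[nm]]$design,
                  file.path(config$outDir, paste0("design_", nm, ".csv")))
      write.csv(runs[[nm]]$trace,
                file.path(config$outDir, paste0("trace_", nm, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = config$seed, baseline = as.list(baseline),
           runs = lapply(runs, function(r)
             list(predictor = r$predictor, task = r$task, k = r$k,
                  mukv = r$mukv))),
      file.path(config$outDir, "design_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
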