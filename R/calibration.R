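## Parameter estimation: variance-weighted least squares, derivative-free
## pattern search (mesh/poll), multi-start, and the in vitro -> in vivo
## translation policy.

#' Construct a calibration dataset
#'
#' Wraps a datapoint table into a \code{\linkS4class{CalibrationDataset}},
#' applying the dispersion imputation rule: points with a missing or zero
#' standard deviation receive sd = 10% of the mean.
#'
#' @param points data.frame with columns condition, readout, time, mean,
#'   and optionally dose, sd, n, norm, weight.
#' @param source "calibration" or "validation".
#' @return a \code{CalibrationDataset}.
#' @export
calibrationDataset <- function(points, source = c("calibration",
                                                  "validation")) {
  source <- match.arg(source)
  if (is.null(points$dose)) points$dose <- 0
  if (is.null(points$n)) points$n <- 1L
  if (is.null(points$norm)) points$norm <- "none"
  if (is.null(points$weight)) points$weight <- 1
  if (is.null(points$sd)) points$sd <- NA_real_
  miss <- is.na(points$sd) | points$sd <= 0
  points$sd[miss] <- 0.1 * abs(points$mean[miss])
  points$sd[points$sd <= 0] <- 0.1   # zero-mean points: absolute floor
  new("CalibrationDataset", points = points, source = source)
}

#' Variance-weighted least-squares loss
#'
#' \code{sum(weight ((sim - mean) / sd)^2)} over all datapoints; simulation
#' failures at a point contribute a large finite penalty.
#'
#' @param sim simulated values aligned to the dataset rows.
#' @param dataset a \code{CalibrationDataset}.
#' @param penalty value charged per non-finite simulated point.
#' @return scalar loss.
#' @export
objectiveLoss <- function(sim, dataset, penalty = 1e6) {
  pts <- dataset@points
  stopifnot(length(sim) == nrow(pts))
  bad <- !is.finite(sim)
  r <- pts$weight * ((sim - pts$mean) / pts$sd)^2
  sum(r[!bad]) + penalty * sum(bad)
}

#' Derivative-free pattern search (mesh/poll)
#'
#' Coordinate poll search with an accelerating pattern move along the last
#' successful direction, mesh contraction (x0.5) on a failed sweep, a
#' starting mesh of 25% of the box width, and convergence when the mesh
#' drops below 1e-6 of the box width. \code{expand} > 1 re-expands the
#' mesh after successful sweeps (classic GPS); the default keeps the mesh
#' (compass search), which traverses the narrow correlated valleys of
#' ODE-calibration objectives much more reliably. The incumbent loss is
#' monotone non-increasing and the search is deterministic given the
#' start.
#'
#' @param fn objective function of a numeric vector.
#' @param start,lower,upper start point and box bounds (named vectors).
#' @param maxit iteration (poll-sweep) budget.
#' @param meshTol convergence mesh size relative to the box width.
#' @param expand mesh expansion factor after a successful sweep.
#' @return list(par, value, trace, converged, evals).
#' @export
patternSearch <- function(fn, start, lower, upper, maxit = 400,
                          meshTol = 1e-6, expand = 1) {
  stopifnot(length(start) == length(lower), length(lower) == length(upper),
            all(is.finite(c(lower, upper))), all(upper > lower))
  x <- pmin(pmax(start, lower), upper)
  width <- upper - lower
  mesh <- 0.25
  f <- fn(x)
  evals <- 1L
  trace <- f
  for (it in seq_len(maxit)) {
    xPrev <- x
    improved <- FALSE
    for (j in seq_along(x)) {
      for (sgn in c(1, -1)) {
        xt <- x
        xt[j] <- min(max(x[j] + sgn * mesh * width[j], lower[j]), upper[j])
        if (xt[j] == x[j]) next
        ft <- fn(xt)
        evals <- evals + 1L
        if (ft < f) {
          x <- xt; f <- ft; improved <- TRUE
          break
        }
      }
    }
    if (improved) {
      ## pattern move: repeat the successful combined step while it pays
      repeat {
        xt <- pmin(pmax(x + (x - xPrev), lower), upper)
        if (all(xt == x)) break
        ft <- fn(xt)
        evals <- evals + 1L
        if (ft < f) { xPrev <- x; x <- xt; f <- ft } else break
      }
    }
    trace <- c(trace, f)
    mesh <- if (improved) min(mesh * expand, 0.25) else mesh * 0.5
    if (mesh < meshTol) break
  }
  list(par = x, value = f, trace = trace, converged = mesh < meshTol,
       evals = evals)
}

#' Fit specification
#'
#' @param free named list of c(lower, upper) bounds for the free
#'   parameters.
#' @param start optional named start vector (defaults to box midpoint on a
#'   log scale).
#' @param nStarts number of multi-start points (seeded Latin hypercube).
#' @param seed RNG seed for the multi-start design.
#' @param maxit pattern-search budget per start.
#' @param weights reserved for per-dataset weighting.
#' @param logScale search in log-parameter space (multiplicative mesh;
#'   default TRUE, suited to positive rate parameters).
#' @return list of class "qsp_fitspec".
#' @export
fitSpec <- function(free, start = NULL, nStarts = 8, seed = 0,
                    maxit = 200, weights = NULL, logScale = TRUE) {
  stopifnot(is.list(free), length(free) >= 0)
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] <= 0 || b[2] <= b[1])
      stop("bounds for '", nm, "' must be finite, positive and increasing",
           call. = FALSE)
  }
  if (!is.null(start)) {
    if (!all(names(free) %in% names(start)))
      stop("start must cover all free parameters", call. = FALSE)
    start <- start[names(free)]
  }
  structure(list(free = free, start = start, nStarts = nStarts,
                 seed = seed, maxit = maxit, weights = weights,
                 logScale = logScale),
            class = "qsp_fitspec")
}

#' Fit model parameters to calibration data
#'
#' Minimizes the variance-weighted loss over the free parameters with
#' multi-start pattern search. \code{simulator(theta)} must return
#' simulated values aligned to the dataset rows, where \code{theta} is the
#' named free-parameter vector.
#'
#' @param spec a \code{\link{fitSpec}}.
#' @param dataset a \code{CalibrationDataset}.
#' @param simulator function(theta) -> simulated values.
#' @return list(par, value, trace, starts, converged).
#' @export
fitModel <- function(spec, dataset, simulator) {
  stopifnot(inherits(spec, "qsp_fitspec"))
  if (length(spec$free) == 0L) {
    sim <- simulator(numeric(0))
    return(list(par = numeric(0), value = objectiveLoss(sim, dataset),
                trace = NULL, starts = 0L, converged = TRUE))
  }
  lower <- vapply(spec$free, `[`, 0, 1)
  upper <- vapply(spec$free, `[`, 0, 2)
  names(lower) <- names(upper) <- names(spec$free)
  tf <- if (spec$logScale) log else identity
  itf <- if (spec$logScale) exp else identity
  obj <- function(x) {
    x <- itf(x)
    names(x) <- names(spec$free)
    sim <- tryCatch(simulator(x), error = function(e) NULL)
    if (is.null(sim)) return(1e8)
    objectiveLoss(sim, dataset)
  }
  starts <- list()
  if (!is.null(spec$start)) starts[[1]] <- tf(unlist(spec$start))
  nRand <- max(0L, spec$nStarts - length(starts))
  if (nRand > 0) {
    set.seed(.resolveSeed(spec$seed))
    u <- lhs::randomLHS(nRand, length(lower))
    for (i in seq_len(nRand))
      starts[[length(starts) + 1L]] <-
        tf(exp(log(lower) + u[i, ] * (log(upper) - log(lower))))
  }
  best <- NULL
  for (st in starts) {
    res <- patternSearch(obj, st, tf(lower), tf(upper), maxit = spec$maxit)
    if (is.null(best) || res$value < best$value) best <- res
  }
  best$par <- itf(best$par)
  names(best$par) <- names(spec$free)
  best$starts <- length(starts)
  if (!best$converged)
    warning("pattern search exhausted its iteration budget; returning ",
            "incumbent", call. = FALSE)
  best
}

## parameters that may change between in vitro and in vivo settings
.translatable <- c("umax", "dmax", "w14_dm1", "w14_dxd", "w15",
                   "n14_dm1", "n14_dxd", "km14_dm1", "km14_dxd")

#' In vitro to in vivo translation of growth/death parameters
#'
#' Re-estimates only the tumor proliferation/death parameters (umax, dmax,
#' the drug-induced death stimuli w14/w15 and their Hill constants) against
#' in vivo datasets, holding every signal-transduction, drug-target and
#' intracellular drug-processing parameter bit-identical. Control and
#' treatment arms are fitted simultaneously; for a dataset containing only
#' a control arm, only umax is adjusted.
#'
#' @param cellParams full named parameter vector from the cell-level
#'   calibration.
#' @param dataset in vivo \code{CalibrationDataset} (empty points =
#'   identity).
#' @param simulatorFactory function(paramVec) -> simulated values aligned
#'   to dataset rows; receives the full parameter vector.
#' @param free subset of translatable parameters to re-estimate.
#' @param bounds named list of c(lower, upper); defaults to
#'   [0.1x, 10x] of the current values.
#' @param ... passed to \code{\link{fitSpec}}.
#' @return list(params = updated full vector, fit = fit result).
#' @export
translateInVivo <- function(cellParams, dataset, simulatorFactory,
                            free = c("umax", "dmax", "w14_dm1", "w15"),
                            bounds = NULL, ...) {
  bad <- setdiff(free, .translatable)
  if (length(bad))
    stop("policy violation: cannot free signaling parameter(s) ",
         paste(bad, collapse = ", "), " during in vivo translation",
         call. = FALSE)
  if (nrow(dataset@points) == 0L)
    return(list(params = cellParams, fit = NULL))
  controlOnly <- all(dataset@points$condition %in%
                       c("control", "vehicle"))
  if (controlOnly) free <- "umax"
  if (is.null(bounds))
    bounds <- lapply(stats::setNames(free, free), function(nm)
      c(0.1 * cellParams[[nm]], 10 * cellParams[[nm]]))
  spec <- fitSpec(bounds, start = cellParams[free], ...)
  sim <- function(theta) {
    pv <- cellParams
    pv[names(theta)] <- theta
    simulatorFactory(pv)
  }
  fit <- fitModel(spec, dataset, sim)
  out <- cellParams
  out[names(fit$par)] <- fit$par
  list(params = out, fit = fit)
}
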