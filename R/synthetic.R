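## Synthetic-data generator: every data modality the calibration pipeline
## consumes, produced from the model itself with known ground-truth
## parameters, so calibration and uncertainty machinery can be tested
## end-to-end without external data.

#' Specify a synthetic fixture
#'
#' @param modality one of "phospho_timecourse", "phospho_doseresponse",
#'   "viability", "pk", "tumor_volume".
#' @param truth named list of true parameter overrides applied on top of
#'   the calibrated baseline (recorded with the fixture for recovery
#'   tests).
#' @param design modality-specific design list:
#'   \describe{
#'     \item{phospho_timecourse}{stim (stimulus), readout, times (h),
#'       norm ("max"/"control")}
#'     \item{phospho_doseresponse}{drug, doses (nM), time (h), readout,
#'       norm}
#'     \item{viability}{drug, doses, duration (h)}
#'     \item{pk}{drug, dose (mg/kg), times (h)}
#'     \item{tumor_volume}{arms: named list of Regimen (must include
#'       "control"), days (measurement days, default every 3), followUp,
#'       startVolume}
#'   }
#' @param n replicates per datapoint (default 3).
#' @param noise list: \code{blot_sd} (multiplicative lognormal sd for
#'   densitometry readouts), \code{volume_cv} (Gaussian cv for volumes),
#'   \code{pk_cv} (proportional PK error).
#' @param seed RNG seed.
#' @param inVivo logical; use in vivo growth parameters.
#' @return list of class "qsp_fixturespec".
#' @export
fixtureSpec <- function(modality = c("phospho_timecourse",
                                     "phospho_doseresponse", "viability",
                                     "pk", "tumor_volume"),
                        truth = list(), design = list(), n = 3,
                        noise = list(blot_sd = 0.15, volume_cv = 0.1,
                                     pk_cv = 0.1),
                        seed = 0, inVivo = FALSE) {
  modality <- match.arg(modality)
  stopifnot(n >= 1, all(unlist(noise) >= 0))
  if (length(design) == 0L)
    design <- switch(modality,
      phospho_timecourse = list(stim = stimulus(EGF = 100 / 6.2),
                                readout = "pEGFR",
                                times = c(0.25, 0.5, 1, 2, 4, 8, 24),
                                norm = "max"),
      phospho_doseresponse = list(drug = "pyrotinib",
                                  doses = c(0, 5, 10, 20, 40, 80),
                                  time = 1, readout = "pERK",
                                  norm = "control"),
      viability = list(drug = "lapatinib",
                       doses = c(0, 10, 30, 100, 300, 1000),
                       duration = 72),
      pk = list(drug = "tdm1", dose = 3,
                times = c(1, 4, 8, 24, 48, 96, 168, 336, 504)),
      tumor_volume = list(
        arms = list(control = regimen(),
                    treated = regimen(regimenArm("lapatinib", 100, "qd"))),
        days = seq(0, 21, by = 3), followUp = 22, startVolume = 80))
  structure(list(modality = modality, truth = truth, design = design,
                 n = n, noise = noise, seed = seed, inVivo = inVivo),
            class = "qsp_fixturespec")
}

.truthNetwork <- function(spec) {
  g <- growthDeathParams(inVivo = spec$inVivo)
  net <- buildNetwork(cellLineConfig("SKBR3", growth = g),
                      inVitro = !spec$inVivo)
  for (nm in names(spec$truth)) net@params[nm] <- spec$truth[[nm]]
  net
}

#' Generate a synthetic calibration fixture
#'
#' Simulates the model at the fixture's true parameters, applies the
#' modality's noise model (multiplicative lognormal for densitometry-style
#' readouts, Gaussian cv for tumor volumes, proportional error for PK) to
#' n replicates per datapoint, and returns a
#' \code{\linkS4class{CalibrationDataset}} whose attribute \code{"truth"}
#' records the generating parameters. With zero noise the dataset means
#' equal the model output exactly. Reproducible bit-for-bit given a seed;
#' different seeds share the identical design.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return a \code{CalibrationDataset} with attributes "truth" and
#'   "spec".
#' @export
generateFixture <- function(spec) {
  stopifnot(inherits(spec, "qsp_fixturespec"))
  d <- spec$design
  clean <- switch(spec$modality,
    phospho_timecourse = {
      net <- .truthNetwork(spec)
      ss <- initializeSteadyState(net)
      tr <- simulateTimecourse(net, ss, d$stim, max(d$times), dt = 0.25)
      v <- stats::approx(trajTimes(tr), readout(tr, d$readout),
                         xout = d$times)$y
      v <- normalizeReadout(v, d$norm)
      data.frame(condition = "timecourse", readout = d$readout,
                 time = d$times, dose = 0, mean = v, norm = d$norm)
    },
    phospho_doseresponse = {
      net <- .truthNetwork(spec)
      ss <- initializeSteadyState(net)
      v <- vapply(d$doses, function(ds) {
        stim <- stimulus(); stim[[d$drug]] <- ds
        tr <- simulateTimecourse(net, ss, stim, d$time, dt = d$time / 8)
        ro <- readout(tr, d$readout)
        ro[length(ro)]
      }, 0)
      v <- normalizeReadout(v, d$norm,
                            controlIndex = which(d$doses == 0)[1])
      data.frame(condition = paste0(d$drug, "_doseresponse"),
                 readout = d$readout, time = d$time, dose = d$doses,
                 mean = v, norm = d$norm)
    },
    viability = {
      net <- .truthNetwork(spec)
      v <- runViability(net, d$drug, d$doses, d$duration)
      data.frame(condition = paste0(d$drug, "_viability"),
                 readout = "viability", time = d$duration,
                 dose = v$dose, mean = v$viability, norm = "control")
    },
    pk = {
      ev <- doseEvents(d$drug, d$dose, 0)
      tab <- simulatePK(pkParams(d$drug), ev, max(d$times), dt = 0.25)
      v <- stats::approx(tab$time, tab$conc, xout = d$times)$y
      data.frame(condition = paste0(d$drug, "_pk"), readout = "conc",
                 time = d$times, dose = d$dose, mean = v, norm = "none")
    },
    tumor_volume = {
      net <- .truthNetwork(spec)
      do.call(rbind, lapply(names(d$arms), function(arm) {
        res <- runXenograft(net, d$arms[[arm]], d$followUp,
                            d$startVolume)
        v <- stats::approx(res$day, res$volume, xout = d$days)$y
        data.frame(condition = arm, readout = "volume", time = d$days,
                   dose = 0, mean = v, norm = "none")
      }))
    })
  ## replicate noise
  set.seed(.resolveSeed(spec$seed))
  noisy <- clean
  reps <- matrix(NA_real_, nrow(clean), spec$n)
  for (i in seq_len(nrow(clean))) {
    mu <- clean$mean[i]
    reps[i, ] <- switch(spec$modality,
      tumor_volume = stats::rnorm(spec$n, mu,
                                  spec$noise$volume_cv * abs(mu)),
      pk = stats::rnorm(spec$n, mu, spec$noise$pk_cv * abs(mu)),
      ## densitometry-style modalities: ratio-scale, lognormal
      mu * stats::rlnorm(spec$n, -spec$noise$blot_sd^2 / 2,
                         spec$noise$blot_sd))
  }
  noisy$mean <- rowMeans(reps)
  noisy$sd <- apply(reps, 1, stats::sd)
  noisy$sd[!is.finite(noisy$sd) | noisy$sd <= 0] <- NA
  noisy$n <- spec$n
  zeroNoise <- switch(spec$modality,
    tumor_volume = spec$noise$volume_cv == 0,
    pk = spec$noise$pk_cv == 0,
    spec$noise$blot_sd == 0)
  if (zeroNoise) noisy$mean <- clean$mean
  ds <- calibrationDataset(noisy)
  attr(ds, "truth") <- spec$truth
  attr(ds, "spec") <- spec
  attr(ds, "clean") <- clean$mean
  ds
}

#' Build a parameter-recovery suite
#'
#' Generates (fixture, fit specification) pairs for the requested free
#' parameters and noise levels, all derived deterministically from the
#' seed, plus a runner that fits each pair and reports per-parameter bias
#' and RMSE.
#'
#' @param free character vector of parameters to recover (must exist in
#'   the parameter template).
#' @param noiseLevels numeric vector of noise levels (volume cv for
#'   tumor-volume fixtures).
#' @param fixture base \code{\link{fixtureSpec}} (default: two-arm
#'   xenograft).
#' @param foldLo,foldHi fit bounds relative to truth.
#' @param seed RNG seed.
#' @param nStarts,maxit fitting effort per pair.
#' @return list(pairs = list of (spec, fitspec), run = function()
#'   returning a summary data.frame with bias and RMSE per parameter).
#' @export
makeRecoverySuite <- function(free, noiseLevels = c(0, 0.1),
                              fixture = NULL, foldLo = 0.25, foldHi = 4,
                              seed = 0, nStarts = 2, maxit = 60) {
  bad <- setdiff(free, names(paramTemplate()))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(fixture))
    fixture <- fixtureSpec("tumor_volume", inVivo = TRUE)
  pairs <- list()
  set.seed(.resolveSeed(seed))
  seeds <- sample.int(1e6, length(noiseLevels))
  base <- paramTemplate()
  for (i in seq_along(noiseLevels)) {
    fs <- fixture
    fs$noise$volume_cv <- noiseLevels[i]
    fs$seed <- seeds[i]
    truthVals <- if (length(free))
      stats::setNames(as.list(
        if (fs$inVivo) unlist(growthDeathParams(inVivo = TRUE))[free]
        else base[free]), free)
    else list()
    ## keep entries that are genuine growth parameters at their in
    ## vivo/in vitro values
    fs$truth <- truthVals
    bounds <- lapply(truthVals, function(v) c(foldLo * v, foldHi * v))
    pairs[[i]] <- list(spec = fs,
                       fitspec = fitSpec(bounds, seed = seeds[i],
                                         nStarts = nStarts,
                                         maxit = maxit))
  }
  run <- function() {
    res <- lapply(pairs, function(pr) {
      ds <- generateFixture(pr$spec)
      sim <- xenograftSimulator(pr$spec, names(pr$fitspec$free))
      if (length(pr$fitspec$free) == 0L)
        return(data.frame(parameter = character(), truth = numeric(),
                          estimate = numeric(), noise = numeric()))
      fit <- fitModel(pr$fitspec, ds, sim)
      data.frame(parameter = names(fit$par),
                 truth = unlist(pr$spec$truth),
                 estimate = unname(fit$par),
                 noise = pr$spec$noise$volume_cv)
    })
    res <- do.call(rbind, res)
    if (nrow(res)) {
      res$relerr <- res$estimate / res$truth - 1
    }
    res
  }
  list(pairs = pairs, run = run)
}

#' Simulator closure for tumor-volume fixtures
#'
#' Returns a function(theta) that re-simulates the fixture's xenograft
#' arms with the free parameters set to \code{theta} and returns predicted
#' volumes aligned to the fixture's datapoint rows (the form
#' \code{\link{fitModel}} expects).
#'
#' @param spec a tumor_volume \code{\link{fixtureSpec}}.
#' @param free names of the free parameters.
#' @return function(theta) -> numeric vector.
#' @export
xenograftSimulator <- function(spec, free) {
  stopifnot(spec$modality == "tumor_volume")
  d <- spec$design
  base <- .truthNetwork(spec)  # design-matched network
  function(theta) {
    net <- base
    net@params[free] <- theta
    unlist(lapply(names(d$arms), function(arm) {
      res <- runXenograft(net, d$arms[[arm]], d$followUp, d$startVolume)
      stats::approx(res$day, res$volume, xout = d$days)$y
    }))
  }
}


#' Staged parameter recovery from synthetic xenograft fixtures
#'
#' End-to-end recovery harness for the growth/death parameters: generates
#' a three-arm xenograft fixture (vehicle control, T-DM1 30 mg/kg q3w,
#' capecitabine 400 mg/kg d1-d14; 60-day follow-up, measurements every 3
#' days) at the known in vivo parameter truth, then re-estimates the
#' parameters in the staged order used for in vivo translation: umax and
#' dmax from the control curve, then the T-DM1 death stimulus w14 and the
#' 5-FU death stimulus w15 from their respective arms with the growth
#' parameters held at the stage-1 estimates. Optionally bootstraps the
#' datapoint means to produce interval estimates.
#'
#' @param noiseCv volume measurement cv (0 = noiseless).
#' @param seed RNG seed.
#' @param followUp study length in days.
#' @param maxit pattern-search budget for the noiseless/staged fits.
#' @param nBoot number of bootstrap resamples (0 = none).
#' @param bootMaxit pattern-search budget per bootstrap refit.
#' @return list(truth, estimates, relerr, boot) where boot (if any) is the
#'   nBoot x 4 matrix of resampled estimates.
#' @export
xenograftRecovery <- function(noiseCv = 0, seed = 0, followUp = 60,
                              maxit = 400, nBoot = 0, bootMaxit = 60) {
  arms <- list(control = regimen(),
               tdm1 = regimen(regimenArm("tdm1", 30, "q3w")),
               capecitabine = regimen(regimenArm("capecitabine", 400,
                                                 "d1-d14")))
  g <- growthDeathParams(inVivo = TRUE)
  truth <- unlist(g)[c("umax", "dmax", "w14_dm1", "w15")]
  fx <- fixtureSpec("tumor_volume", inVivo = TRUE,
    design = list(arms = arms, days = seq(0, followUp, by = 3),
                  followUp = followUp + 1, startVolume = 80),
    noise = list(blot_sd = 0, volume_cv = noiseCv, pk_cv = 0),
    seed = seed)
  fx$truth <- as.list(truth)
  ds <- generateFixture(fx)
  pts <- datasetPoints(ds)
  ## dispersion convention: 10%-of-mean imputation (replicate SDs at n = 3
  ## are too unstable to weight by)
  pts$sd <- 0.1 * abs(pts$mean)

  stagedFit <- function(points, start, maxitStage) {
    sub <- function(cond) {
      keep <- points$condition == cond
      new("CalibrationDataset", points = points[keep, ],
          source = "calibration")
    }
    est <- start
    ## stage 1: growth parameters from the control curve
    fxc <- fx
    fxc$design$arms <- arms["control"]
    f1 <- suppressWarnings(fitModel(
      fitSpec(lapply(as.list(truth[c("umax", "dmax")]),
                     function(v) c(0.25 * v, 4 * v)),
              start = as.list(est[c("umax", "dmax")]), nStarts = 1,
              maxit = maxitStage),
      sub("control"), xenograftSimulator(fxc, c("umax", "dmax"))))
    est[c("umax", "dmax")] <- f1$par
    ## stages 2-3: one death stimulus per treated arm, growth fixed
    for (stage in list(c("tdm1", "w14_dm1"), c("capecitabine", "w15"))) {
      cond <- stage[1]; parm <- stage[2]
      fxa <- fx
      fxa$design$arms <- arms[cond]
      fxa$truth <- as.list(est[c("umax", "dmax")])
      simFn <- xenograftSimulator(fxa, parm)
      f <- suppressWarnings(fitModel(
        fitSpec(stats::setNames(list(c(0.25 * truth[[parm]],
                                       4 * truth[[parm]])), parm),
                start = stats::setNames(list(est[[parm]]), parm),
                nStarts = 1, maxit = maxitStage),
        sub(cond), simFn))
      est[parm] <- f$par
    }
    est
  }

  start0 <- truth * c(1.6, 0.6, 1.7, 0.5)
  est <- stagedFit(pts, start0, maxit)
  out <- list(truth = truth, estimates = est,
              relerr = est / truth - 1, boot = NULL)
  if (nBoot > 0) {
    set.seed(.resolveSeed(seed))
    seeds <- sample.int(1e6, nBoot)
    boot <- matrix(NA_real_, nBoot, 4,
                   dimnames = list(NULL, names(truth)))
    for (b in seq_len(nBoot)) {
      set.seed(seeds[b])
      ptsB <- pts
      ptsB$mean <- stats::rnorm(nrow(pts), pts$mean, pts$sd)
      boot[b, ] <- tryCatch(stagedFit(ptsB, est, bootMaxit),
                            error = function(e) rep(NA_real_, 4))
    }
    out$boot <- boot
  }
  out
}
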