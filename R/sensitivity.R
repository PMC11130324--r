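## Global sensitivity (PRCC on Latin-hypercube samples, total-order Sobol
## indices) and bootstrap parameter-uncertainty analysis.

#' Latin hypercube parameter sample
#'
#' Stratified uniform sample: each parameter's marginal places exactly one
#' point in each of n equal-probability strata. Deterministic given the
#' seed.
#'
#' @param n number of samples.
#' @param ranges named list of c(lower, upper) per parameter.
#' @param seed RNG seed.
#' @return n x k data.frame of parameter values.
#' @export
lhsSample <- function(n, ranges, seed = 0) {
  k <- length(ranges)
  stopifnot(n >= k, k >= 1)
  for (b in ranges)
    if (length(b) != 2 || any(!is.finite(b)) || b[2] <= b[1])
      stop("ranges must be finite, increasing pairs", call. = FALSE)
  set.seed(.resolveSeed(seed))
  u <- lhs::randomLHS(n, k)
  out <- as.data.frame(mapply(function(uu, b) b[1] + uu * (b[2] - b[1]),
                              as.data.frame(u), ranges))
  names(out) <- names(ranges)
  out
}

#' Sensitivity range specification around a baseline
#'
#' Ranges of [lowFold x, highFold x] around baseline parameter values (the
#' convention for the tumor-volume sensitivity analyses is one-half to
#' two-fold).
#'
#' @param baseline named numeric vector of baseline values.
#' @param lowFold,highFold fold-range below/above baseline.
#' @return named list of c(lower, upper).
#' @export
foldRanges <- function(baseline, lowFold = 0.5, highFold = 2) {
  lapply(as.list(baseline), function(v) c(lowFold * v, highFold * v))
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms inputs and output, regresses each parameter's ranks and
#' the output's ranks on the ranks of all other parameters, and correlates
#' the residuals; p-values from the t-statistic on the residual
#' correlation. Samples with non-finite outputs are dropped (at most 5%
#' by contract). Significance: |PRCC| > 0.05 with Bonferroni-corrected
#' p < alpha.
#'
#' @param samples n x k data.frame of parameter values.
#' @param outputs length-n numeric model outputs.
#' @param alpha significance level before Bonferroni correction.
#' @return data.frame(parameter, prcc, p, significant), ordered by |prcc|.
#' @export
prcc <- function(samples, outputs, alpha = 0.01) {
  stopifnot(nrow(samples) == length(outputs))
  ok <- is.finite(outputs)
  if (mean(ok) < 0.95)
    warning(sprintf("%.1f%% of outputs non-finite; dropped",
                    100 * mean(!ok)), call. = FALSE)
  X <- samples[ok, , drop = FALSE]
  y <- outputs[ok]
  n <- length(y)
  k <- ncol(X)
  if (stats::sd(y) == 0)
    stop("constant output: PRCC undefined", call. = FALSE)
  R <- apply(X, 2, rank)
  ry <- rank(y)
  out <- data.frame(parameter = colnames(X), prcc = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    others <- R[, -j, drop = FALSE]
    rx <- stats::residuals(stats::lm.fit(cbind(1, others), R[, j]))
    rr <- stats::residuals(stats::lm.fit(cbind(1, others), ry))
    if (stats::sd(rx) == 0 || stats::sd(rr) == 0) next
    r <- stats::cor(rx, rr)
    df <- n - 2 - (k - 1)
    tstat <- r * sqrt(df / max(1 - r^2, 1e-12))
    out$prcc[j] <- r
    out$p[j] <- 2 * stats::pt(-abs(tstat), df)
  }
  out$significant <- !is.na(out$prcc) & abs(out$prcc) > 0.05 &
    out$p < alpha / k
  out[order(-abs(out$prcc)), ]
}

#' Total-order Sobol indices (Saltelli sampling, Jansen estimator)
#'
#' Generates the A/B/AB_i radial design from two seeded Latin hypercube
#' matrices and estimates total-order indices
#' \code{ST_i = mean((fA - fAB_i)^2) / (2 Var(f))}, with bootstrap
#' confidence intervals over the base samples.
#'
#' @param fn function taking a named parameter vector (or a one-row
#'   data.frame coerced to vector) and returning a scalar output.
#' @param ranges named list of c(lower, upper).
#' @param n base sample size (total model runs = n (k + 2)).
#' @param seed RNG seed.
#' @param nboot bootstrap replicates for the CI.
#' @return data.frame(parameter, total, lo, hi), ordered by total index.
#' @export
sobolTotal <- function(fn, ranges, n = 512, seed = 0, nboot = 100) {
  k <- length(ranges)
  set.seed(.resolveSeed(seed))
  scale <- function(u) {
    out <- mapply(function(uu, b) b[1] + uu * (b[2] - b[1]),
                  as.data.frame(u), ranges)
    matrix(out, ncol = k, dimnames = list(NULL, names(ranges)))
  }
  A <- scale(lhs::randomLHS(n, k))
  B <- scale(lhs::randomLHS(n, k))
  evalRows <- function(M) apply(M, 1, function(r) fn(stats::setNames(r, names(ranges))))
  fA <- evalRows(A)
  V <- stats::var(c(fA))
  if (!is.finite(V) || V <= 1e-12 * mean(fA)^2)
    stop("output variance is (near) zero; Sobol indices undefined",
         call. = FALSE)
  D <- matrix(NA_real_, n, k, dimnames = list(NULL, names(ranges)))
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    D[, i] <- (fA - evalRows(ABi))^2
  }
  total <- colMeans(D) / (2 * V)
  set.seed(.resolveSeed(seed) + 1L)
  bt <- replicate(nboot, {
    idx <- sample.int(n, replace = TRUE)
    colMeans(D[idx, , drop = FALSE]) / (2 * stats::var(fA[idx]))
  })
  if (k == 1L) bt <- matrix(bt, nrow = 1)
  out <- data.frame(parameter = names(ranges), total = total,
                    lo = apply(bt, 1, stats::quantile, 0.025),
                    hi = apply(bt, 1, stats::quantile, 0.975))
  out[order(-out$total), ]
}

#' Bootstrap parameter-uncertainty analysis
#'
#' Resamples the calibration datapoint means from Normal(mean, sd) --
#' with the 10%-of-mean dispersion imputation already applied by
#' \code{\link{calibrationDataset}} -- refits the selected parameters for
#' each resample within [0.1x, 10x] of baseline, and reports the
#' per-parameter relative-to-baseline distributions.
#'
#' @param dataset a \code{CalibrationDataset}.
#' @param simulator function(theta) -> simulated values (as in
#'   \code{\link{fitModel}}).
#' @param baseline named baseline values of the selected parameters.
#' @param nResamples number of resampled datasets (convention: 50).
#' @param seed RNG seed.
#' @param foldLo,foldHi per-estimate bounds relative to baseline.
#' @param ... passed to \code{\link{fitSpec}} (e.g. nStarts, maxit).
#' @return list(estimates = nResamples x k matrix (NA rows mark failed
#'   fits), relative = estimates / baseline, baseline, failures).
#' @export
bootstrapUncertainty <- function(dataset, simulator, baseline,
                                 nResamples = 50, seed = 0, foldLo = 0.1,
                                 foldHi = 10, ...) {
  pts <- dataset@points
  k <- length(baseline)
  est <- matrix(NA_real_, nResamples, k,
                dimnames = list(NULL, names(baseline)))
  bounds <- lapply(as.list(baseline), function(v) c(foldLo * v, foldHi * v))
  set.seed(.resolveSeed(seed))
  seeds <- sample.int(1e6, nResamples)
  failures <- 0L
  for (b in seq_len(nResamples)) {
    set.seed(seeds[b])
    ptsB <- pts
    ptsB$mean <- stats::rnorm(nrow(pts), pts$mean, pts$sd)
    dsB <- new("CalibrationDataset", points = ptsB,
               source = dataset@source)
    fit <- tryCatch(
      fitModel(fitSpec(bounds, start = baseline, seed = seeds[b], ...),
               dsB, simulator),
      error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    est[b, ] <- fit$par[names(baseline)]
  }
  list(estimates = est, relative = sweep(est, 2, unlist(baseline), "/"),
       baseline = baseline, failures = failures)
}

#' Default parameter set for the tumor-volume sensitivity analyses
#'
#' Twenty parameters spanning tumor growth/death, the Raf/MAPK and
#' PI3K/AKT cascades, receptor transphosphorylation, NRG1-HER3 binding and
#' ADC payload processing.
#'
#' @return character vector of parameter names.
#' @export
sensitivityParameters <- function() {
  c("umax", "dmax", "kon_Raf", "koff_Raf", "kon_ERK", "koff_ERK",
    "w7", "w8", "w11", "wAKT", "kon_PI3K", "koff_PI3K", "k8on", "k8off",
    "kphos", "kdeph", "kint_ADC1", "kdeg_ADC_2_1", "kout_PL", "kper_PL")
}

#' Input conditions for the tumor-volume sensitivity analyses
#'
#' The six analysis conditions: no external stimuli, NRG1 overexpression,
#' lapatinib + capecitabine, pyrotinib + capecitabine, single-agent T-DM1
#' and single-agent T-DXd. The NRG1 overexpression condition uses a
#' constant 1 ng/mL bath, an autocrine-level tissue tone at which
#' receptor binding is still rate-limiting so the binding rate k8on
#' retains leverage (the resistance-phenotype simulations use the
#' saturating 50 ng/mL in vitro level instead).
#'
#' @param name condition name.
#' @return list(stim, regimen).
#' @export
sensitivityCondition <- function(name = c("none", "NRG1_over", "lap+cap",
                                          "pyr+cap", "TDM1", "TDXd")) {
  name <- match.arg(name)
  switch(name,
    none = list(stim = stimulus(), regimen = regimen()),
    NRG1_over = list(stim = stimulus(NRG1 = 1 / 7.5), regimen = regimen()),
    `lap+cap` = list(stim = stimulus(),
                     regimen = regimen(regimenArm("lapatinib", 100, "qd"),
                                       regimenArm("capecitabine", 400,
                                                  "d1-d14"))),
    `pyr+cap` = list(stim = stimulus(),
                     regimen = regimen(regimenArm("pyrotinib", 30, "qd"),
                                       regimenArm("capecitabine", 400,
                                                  "d1-d14"))),
    TDM1 = list(stim = stimulus(),
                regimen = regimen(regimenArm("tdm1", 30, "q3w"))),
    TDXd = list(stim = stimulus(),
                regimen = regimen(regimenArm("tdxd", 10, "q3w"))))
}

#' PRCC sensitivity of tumor volume to model parameters
#'
#' Latin-hypercube samples the selected parameters over
#' [lowFold x, highFold x] of baseline (convention: one-half to two-fold),
#' simulates the xenograft under the chosen input condition for each
#' sample, takes tumor volume at \code{day} as the output, and computes
#' PRCC with significance.
#'
#' @param condition one of the \code{\link{sensitivityCondition}} names.
#' @param n number of LHS samples.
#' @param seed RNG seed.
#' @param parameters parameter names to vary (default the 20-parameter
#'   panel).
#' @param day output day (tumor volume at day 20 by default).
#' @param lowFold,highFold sampling range around baseline.
#' @param network base in vivo network (default calibrated SKBR3
#'   xenograft).
#' @return list(samples, outputs, prcc).
#' @export
tumorSensitivity <- function(condition = "none", n = 500, seed = 0,
                             parameters = sensitivityParameters(),
                             day = 20, lowFold = 0.5, highFold = 2,
                             network = NULL) {
  if (is.null(network))
    network <- buildNetwork(
      cellLineConfig("SKBR3", growth = growthDeathParams(inVivo = TRUE)),
      inVitro = FALSE)
  cond <- sensitivityCondition(condition)
  base <- network@params[parameters]
  samples <- lhsSample(n, foldRanges(base, lowFold, highFold), seed)
  outputs <- vapply(seq_len(n), function(i) {
    net <- network
    net@params[parameters] <- as.numeric(samples[i, ])
    res <- tryCatch(
      runXenograft(net, cond$regimen, day + 1, stim0 = cond$stim),
      error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    res$volume[nrow(res)]
  }, 0)
  list(samples = samples, outputs = outputs,
       prcc = prcc(samples, outputs))
}
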