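test_that("the loss is variance-weighted least squares", {
  ds <- calibrationDataset(data.frame(condition = "a", readout = "y",
                                      time = 1:5, mean = c(1, 2, 3, 4, 5),
                                      sd = c(0.5, 1, 1, 2, 1)))
  expect_equal(objectiveLoss(c(1, 2, 3, 4, 5), ds), 0)
  expect_equal(objectiveLoss(c(1.5, 2, 3, 4, 5), ds), 1)  # off by 1 sd
  set.seed(3)
  sim <- rnorm(5, 3, 2)
  pts <- datasetPoints(ds)
  expect_equal(objectiveLoss(sim, ds),
               sum(((sim - pts$mean) / pts$sd)^2))
  ## non-finite simulation values incur a large finite penalty
  expect_equal(objectiveLoss(c(NA, 2, 3, 4, 5), ds), 1e6)
})

test_that("missing dispersion is imputed as 10% of the mean", {
  ds <- calibrationDataset(data.frame(condition = "a", readout = "y",
                                      time = 1:3, mean = c(10, 20, 30),
                                      sd = c(NA, 0, 2)))
  expect_equal(datasetPoints(ds)$sd, c(1, 2, 2))
})

test_that("pattern search minimizes a convex quadratic to its analytic
           minimum with a monotone trace", {
  fn <- function(x) sum((x - c(2, -1))^2) + 0.5 * x[1] * x[2]
  ## analytic minimum of x'Ax/ - ...: solve gradient = 0
  A <- matrix(c(2, 0.5, 0.5, 2), 2)
  b <- c(4, -2)
  ref <- solve(A, b)
  res <- patternSearch(fn, c(5, 5), c(-10, -10), c(10, 10), maxit = 300)
  expect_equal(res$par, ref, tolerance = 1e-4)
  expect_true(all(diff(res$trace) <= 0))
  expect_true(res$converged)
})

test_that("an already-optimal start is returned unchanged", {
  fn <- function(x) sum(x^2)
  res <- patternSearch(fn, c(0, 0), c(-1, -1), c(1, 1), maxit = 100)
  expect_equal(res$par, c(0, 0))
  expect_equal(res$value, 0)
})

test_that("fitModel recovers growth parameters from noiseless synthetic
           data", {
  fx <- fixtureSpec("tumor_volume", inVivo = TRUE,
    design = list(arms = list(control = regimen()),
                  days = seq(0, 60, by = 3), followUp = 61,
                  startVolume = 80),
    noise = list(blot_sd = 0, volume_cv = 0, pk_cv = 0), seed = 11)
  g <- growthDeathParams(inVivo = TRUE)
  fx$truth <- list(umax = g$umax, dmax = g$dmax)
  ds <- generateFixture(fx)
  sim <- xenograftSimulator(fx, c("umax", "dmax"))
  truth <- unlist(fx$truth)
  fit <- suppressWarnings(fitModel(
    fitSpec(lapply(as.list(truth), function(v) c(0.3 * v, 3 * v)),
            start = as.list(truth * c(1.5, 0.6)), nStarts = 1,
            maxit = 250),
    ds, sim))
  expect_lt(max(abs(fit$par / truth - 1)), 0.05)
})

test_that("refitting with permuted dataset order gives the same
           estimates", {
  fx <- fixtureSpec("tumor_volume", inVivo = TRUE,
    design = list(arms = list(control = regimen()),
                  days = seq(0, 30, by = 3), followUp = 31,
                  startVolume = 80),
    noise = list(blot_sd = 0, volume_cv = 0.05, pk_cv = 0), seed = 2)
  g <- growthDeathParams(inVivo = TRUE)
  fx$truth <- list(umax = g$umax)
  ds <- generateFixture(fx)
  pts <- datasetPoints(ds)
  perm <- rev(seq_len(nrow(pts)))
  dsPerm <- calibrationDataset(pts[perm, ])
  sim <- xenograftSimulator(fx, "umax")
  spec <- fitSpec(list(umax = c(0.1, 0.6)), start = list(umax = 0.35),
                  nStarts = 1, maxit = 60)
  f1 <- suppressWarnings(fitModel(spec, ds, sim))
  f2 <- suppressWarnings(fitModel(spec, dsPerm,
                                  function(th) sim(th)[perm]))
  expect_equal(f1$par, f2$par, tolerance = 1e-10)
})

test_that("in vivo translation honors the parameter policy", {
  base <- paramTemplate()
  expect_error(translateInVivo(base, calibrationDataset(
    data.frame(condition = "control", readout = "volume", time = 1,
               mean = 100, sd = 10)), function(p) 100,
    free = c("umax", "k8on")), "policy violation")
  ## empty dataset: identity
  empty <- new("CalibrationDataset",
               points = data.frame(condition = character(),
                                   readout = character(), time = numeric(),
                                   mean = numeric(), sd = numeric(),
                                   n = integer(), norm = character(),
                                   weight = numeric()),
               source = "calibration")
  out <- translateInVivo(base, empty, function(p) numeric(0))
  expect_identical(out$params, base)
})

test_that("a control-only dataset adjusts umax and nothing else", {
  fx <- fixtureSpec("tumor_volume", inVivo = TRUE,
    design = list(arms = list(control = regimen()),
                  days = seq(0, 21, by = 3), followUp = 22,
                  startVolume = 80),
    noise = list(blot_sd = 0, volume_cv = 0, pk_cv = 0), seed = 1)
  ## data generated at a faster-growing truth than the baseline
  fx$truth <- list(umax = 0.32)
  ds <- generateFixture(fx)
  net <- skbr3Vivo()
  base <- net@params
  simFactory <- function(pv) {
    n2 <- net; n2@params <- pv
    res <- runXenograft(n2, regimen(), 22, 80)
    approx(res$day, res$volume, xout = seq(0, 21, by = 3))$y
  }
  out <- suppressWarnings(translateInVivo(
    base, ds, simFactory, free = c("umax", "dmax", "w15"),
    nStarts = 1, maxit = 80))
  changed <- names(base)[out$params != base]
  expect_identical(changed, "umax")
  expect_equal(unname(out$params[["umax"]]), 0.32, tolerance = 0.05)
})
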