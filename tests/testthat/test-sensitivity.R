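test_that("Latin hypercube samples stratify every marginal", {
  s <- lhsSample(4, list(a = c(1, 2)), seed = 3)
  ## one point in each quartile
  expect_equal(sort(findInterval(s$a, seq(1, 2, by = 0.25),
                                 rightmost.closed = TRUE)), 1:4)
  ## Kolmogorov distance to uniform is bounded by 1/n for LHS
  for (seed in 1:3) {
    s2 <- lhsSample(50, list(a = c(0.5, 2), b = c(1, 10)), seed = seed)
    for (j in 1:2) {
      u <- (s2[[j]] - c(0.5, 1)[j]) / c(1.5, 9)[j]
      ks <- max(abs(sort(u) - (seq_len(50) - 0.5) / 50))
      expect_lte(ks, 1 / 50 + 1e-12)
    }
  }
  ## deterministic given the seed
  expect_identical(lhsSample(16, list(a = c(1, 2), b = c(1, 2)), seed = 7),
                   lhsSample(16, list(a = c(1, 2), b = c(1, 2)), seed = 7))
})

test_that("PRCC attributes a monotone output to its driver and not to
           dummies", {
  set.seed(5)
  X <- lhsSample(300, list(x1 = c(1, 2), x2 = c(1, 2), x3 = c(1, 2)),
                 seed = 5)
  y <- 3 * X$x1 + 0.01 * rnorm(300)
  pr <- prcc(X, y)
  expect_gt(pr$prcc[pr$parameter == "x1"], 0.95)
  expect_true(pr$significant[pr$parameter == "x1"])
  expect_lt(max(abs(pr$prcc[pr$parameter != "x1"])), 0.15)
  expect_false(any(pr$significant[pr$parameter != "x1"]))
})

test_that("PRCC is invariant under strictly monotone output transforms", {
  X <- lhsSample(200, list(x1 = c(1, 2), x2 = c(1, 2)), seed = 8)
  y <- X$x1^2 / X$x2
  p1 <- prcc(X, y)
  p2 <- prcc(X, exp(y))
  expect_equal(p1$prcc, p2$prcc, tolerance = 1e-12)
})

test_that("constant output signals an undefined PRCC", {
  X <- lhsSample(20, list(x1 = c(1, 2), x2 = c(1, 2)), seed = 1)
  expect_error(prcc(X, rep(3, 20)), "constant output")
})

test_that("Sobol total indices recover the analytic variance shares of an
           additive model", {
  fn <- function(x) 3 * x[["x1"]] + 1 * x[["x2"]] + 0 * x[["x3"]]
  res <- sobolTotal(fn, list(x1 = c(1, 2), x2 = c(1, 2), x3 = c(1, 2)),
                    n = 512, seed = 2)
  ## Var = (9 + 1)/12; ST1 = 0.9, ST2 = 0.1, ST3 = 0
  expect_lt(abs(res$total[res$parameter == "x1"] - 0.9), 0.05)
  expect_lt(abs(res$total[res$parameter == "x2"] - 0.1), 0.03)
  expect_lt(res$total[res$parameter == "x3"], 0.02)
  ## analytic values inside the bootstrap CIs
  expect_true(res$lo[res$parameter == "x1"] <= 0.9 &&
                res$hi[res$parameter == "x1"] >= 0.9)
})

test_that("Sobol and PRCC rank the drivers of a shared toy model alike", {
  fn <- function(x) 2 * x[["a"]]^1.5 + 0.4 * x[["b"]] + 0.05 * x[["c"]]
  ranges <- list(a = c(1, 2), b = c(1, 2), c = c(1, 2))
  sb <- sobolTotal(fn, ranges, n = 256, seed = 3)
  X <- lhsSample(300, ranges, seed = 3)
  pr <- prcc(X, apply(X, 1, function(r) fn(as.list(r))))
  expect_identical(sb$parameter, pr$parameter)  # both sorted by influence
})

test_that("bootstrap uncertainty: zero dispersion collapses the
           estimate distribution", {
  pts <- data.frame(condition = "a", readout = "y", time = 1:6,
                    mean = 2 * (1:6), sd = 1e-9)
  ds <- new("CalibrationDataset", points = calibrationDataset(pts)@points,
            source = "calibration")
  sim <- function(theta) theta[["slope"]] * (1:6)
  out <- bootstrapUncertainty(ds, sim, c(slope = 2), nResamples = 6,
                              seed = 1, nStarts = 1, maxit = 40)
  expect_equal(max(out$estimates) - min(out$estimates), 0,
               tolerance = 1e-5)
  expect_equal(unname(out$relative[1, 1]), 1, tolerance = 1e-5)
})

test_that("bootstrap uncertainty covers a known slope under 10% noise", {
  set.seed(12)
  x <- 1:20
  truth <- 3
  ## measured dispersions (10% cv); imputing sd from noisy means instead
  ## would bias the variance-weighted fit downward
  pts <- data.frame(condition = "a", readout = "y", time = x,
                    mean = truth * x * (1 + 0.1 * rnorm(20)),
                    sd = 0.1 * truth * x)
  ds <- calibrationDataset(pts)
  sim <- function(theta) theta[["slope"]] * x
  out <- bootstrapUncertainty(ds, sim, c(slope = 2.5), nResamples = 40,
                              seed = 2, nStarts = 1, maxit = 60)
  q <- quantile(out$estimates[, 1], c(0.025, 0.975), na.rm = TRUE)
  ## the bootstrap distribution brackets the analytic weighted-LS fit of
  ## this dataset, with width on the scale of the analytic standard error
  pts <- datasetPoints(ds)
  w <- 1 / pts$sd^2
  analytic <- sum(w * pts$mean * x) / sum(w * x^2)
  se <- 1 / sqrt(sum(w * x^2))
  expect_gte(analytic, q[[1]] - 1e-9)
  expect_lte(analytic, q[[2]] + 1e-9)
  expect_gt(q[[2]] - q[[1]], 1.5 * se)
  expect_lt(q[[2]] - q[[1]], 6 * se)
  ## and the truth lies within a 3-standard-error band of the estimate
  expect_lt(abs(mean(out$estimates, na.rm = TRUE) - truth), 3 * se)
})
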