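test_that("regimen expansion is deterministic, idempotent and
           order-independent", {
  a <- regimenArm("lapatinib", 100, "qd")
  b <- regimenArm("capecitabine", 400, "d1-d14")
  c3 <- regimenArm("tdm1", 30, "q3w")
  e1 <- expandRegimen(regimen(a, b, c3), 43)
  e2 <- expandRegimen(regimen(c3, b, a), 43)
  expect_identical(e1, e2)
  expect_identical(e1, expandRegimen(regimen(a, b, c3), 43))
  ## schedule semantics on a 21-day cycle
  lap <- e1[e1$drug == "lapatinib", ]
  expect_equal(lap$time, (0:42) * 24)
  cap <- e1[e1$drug == "capecitabine", ]
  expect_equal(cap$time, c(0:13, 21:34, 42) * 24)
  tdm <- e1[e1$drug == "tdm1", ]
  expect_equal(tdm$time, c(0, 21, 42) * 24)
  ## mg/kg -> mg at 20 g body weight
  expect_equal(unique(tdm$amount), 30 * 0.02)
})

test_that("viability is 1 untreated and equals the two-simulation ratio", {
  net <- skbr3Vitro()
  v <- runViability(net, "lapatinib", c(0, 100), 72)
  expect_equal(v$viability[1], 1)
  nEnd <- function(stim) endReadout(stim, "ncell", 72)
  expect_equal(v$viability[2],
               nEnd(stimulus(lapatinib = 100)) / nEnd(stimulus()),
               tolerance = 1e-8)
})

test_that("viability curves are monotone non-increasing in dose", {
  net <- skbr3Vitro()
  for (drug in c("lapatinib", "pyrotinib", "fu", "tdm1", "tdxd")) {
    doses <- switch(drug, fu = c(0, 1e3, 1e4, 1e5),
                    tdm1 = c(0, 0.5, 2, 10), tdxd = c(0, 0.5, 2, 10),
                    c(0, 10, 100, 1000))
    v <- runViability(net, drug, doses, 72)
    expect_true(all(diff(v$viability) <= 1e-9), info = drug)
  }
})

test_that("NRG1 rescues lapatinib-induced viability loss", {
  net <- skbr3Vitro()
  plain <- runViability(net, "lapatinib", c(0, 300), 72)
  nrg <- runViability(net, "lapatinib", c(0, 300), 72,
                      stim0 = applyLigand(stimulus(), "NRG1", 50))
  expect_gt(nrg$viability[2], plain$viability[2] + 0.2)
})

test_that("untreated xenografts grow sigmoidally toward the 2000 mm3
           cap", {
  ctl <- runXenograft(skbr3Vivo(), regimen(), 63)
  expect_equal(ctl$volume[1], 80)
  expect_true(all(diff(ctl$volume) >= -1e-6))
  expect_true(all(ctl$volume <= 2000 + 1e-6))
  ## decelerating late growth (logistic approach)
  d1 <- ctl$volume[35] - ctl$volume[28]
  d2 <- ctl$volume[63] - ctl$volume[56]
  expect_lt(d2, d1)
})

test_that("single-agent TGI at day 20 is non-decreasing in dose", {
  for (drug in c("pyrotinib", "tdm1")) {
    doses <- if (drug == "pyrotinib") c(2, 6, 30) else c(2, 10, 30)
    sched <- if (drug == "pyrotinib") "qd" else "q3w"
    tgi <- vapply(doses, function(d)
      tgiAtDay(regimen(regimenArm(drug, d, sched))), 0)
    expect_true(all(diff(tgi) >= -0.5), info = drug)
  }
})

test_that("TGI formula matches a hand-computed oracle and its edge
           cases", {
  mk <- function(v0, vt, day = 20)
    data.frame(day = c(0, day), volume = c(v0, vt))
  expect_equal(computeTGI(mk(80, 200), mk(80, 1280), 20), 90)
  expect_equal(computeTGI(mk(80, 500), mk(80, 500), 20), 0)
  expect_equal(computeTGI(mk(80, 80), mk(80, 900), 20), 100)
  ## regression below baseline clips at 100
  expect_equal(computeTGI(mk(80, 40), mk(80, 900), 20), 100)
  expect_error(computeTGI(mk(80, 100), mk(80, 80), 20), "not grown")
  ## ratio-of-volumes form
  expect_equal(computeTGI(mk(80, 200), mk(80, 1000), 20,
                          baselineCorrected = FALSE), 80)
})

test_that("readout normalization follows the densitometry conventions", {
  expect_equal(normalizeReadout(c(2, 4, 8), "max"), c(0.25, 0.5, 1))
  expect_equal(normalizeReadout(c(2, 4, 8), "control", 2), c(0.5, 1, 2))
  expect_equal(normalizeReadout(rep(3, 4), "max"), rep(1, 4))
  expect_error(normalizeReadout(c(0, 0), "max"), "> 0")
})

test_that("a regimen with an unparameterized drug is rejected", {
  net <- buildNetwork(cellLineConfig("SKBR3",
                                     growth = growthDeathParams(inVivo = TRUE)),
                      drugs = "lapatinib", inVitro = FALSE)
  expect_error(runXenograft(net, regimen(regimenArm("tdm1", 5, "q3w")), 7),
               "without wired PK")
})

test_that("NRG1 exposure blunts lapatinib's tumor growth inhibition", {
  lap <- regimen(regimenArm("lapatinib", 100, "qd"))
  plain <- tgiAtDay(lap)
  nrg <- tgiAtDay(lap, stim = stimulus(NRG1 = 50 / 7.5))
  expect_lt(nrg, plain - 30)
})

test_that("repeated ADC cycles inhibit at least as much as a single
           dose", {
  one <- runXenograft(skbr3Vivo(),
                      regimen(regimenArm("tdm1", 6, "single")), 43)
  two <- runXenograft(skbr3Vivo(),
                      regimen(regimenArm("tdm1", 6, "q3w")), 43)
  expect_lte(two$volume[43], one$volume[43] + 1e-6)
})
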