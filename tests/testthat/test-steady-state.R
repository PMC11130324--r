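test_that("HER2-overexpressing cells reach a signaling-on steady state", {
  ss <- skbr3VitroSS()
  ## ligand-independent HER2 homo-/heterodimers keep baseline signaling on
  expect_gt(ss[["pD22"]], 0)
  expect_gt(ss[["pD23"]], 0)
  expect_gt(ss[["pAKT"]], 0.2)
  expect_gt(ss[["pERK"]], 0.2)
  ## max relative derivative below the steady-state tolerance
  dy <- qspHER2:::.evalRHS(ss, skbr3Vitro()@params)
  rel <- abs(dy) / pmax(abs(ss), 1e-6)
  rel["NCELL"] <- 0
  expect_lt(max(rel), 1e-8)
})

test_that("steady state is stable over a further 48 h", {
  net <- skbr3Vitro()
  ss <- skbr3VitroSS()
  tr <- simulateTimecourse(net, ss, stimulus(), 48, dt = 4)
  fin <- trajStates(tr)[nrow(trajStates(tr)), ]
  fin["NCELL"] <- ss["NCELL"]
  idx <- ss > 1e-6
  expect_lt(max(abs(fin[idx] / ss[idx] - 1)), 1e-3)
})

test_that("without dimerization there is no phospho-signal at steady
           state", {
  sig <- signalingParams(kon12 = 0, kon22 = 0, kon23 = 0, kon32 = 0,
                         kon42 = 0)
  net <- buildNetwork(cellLineConfig("SKBR3"), signaling = sig)
  ss <- initializeSteadyState(net, maxT = 4000)
  expect_equal(unname(ss[c("D12", "pD12", "D22", "pD22", "D23", "pD23",
                           "D32", "pD32", "D42", "pD42")]), rep(0, 10))
})

test_that("monomer-dimer steady state matches the algebraic equilibrium", {
  ## HER2-only toy: E2* = ksyn2/kdeg2; D22* = kon22 E2*^2 / koff22;
  ## pD22* = D22* kphos/kdeph (full kinase availability)
  cl <- cellLineConfig("her2only",
                       receptors = c(EGFR = 0, HER2 = 2e5, HER3 = 0,
                                     HER4 = 0))
  net <- buildNetwork(cl)
  p <- net@params
  ss <- initializeSteadyState(net)
  e2 <- p[["ksyn2"]] / p[["kdeg2"]]
  d22 <- p[["kon22"]] * e2^2 / p[["koff22"]]
  expect_equal(ss[["E2"]], e2, tolerance = 1e-6)
  expect_equal(ss[["D22"]], d22, tolerance = 1e-6)
  expect_equal(ss[["pD22"]], d22 * p[["kphos"]] / p[["kdeph"]],
               tolerance = 1e-6)
})

test_that("receptor monomers are conserved when turnover is off", {
  net <- skbr3Vitro()
  p <- net@params
  p["f_turnover"] <- 0
  p["bath_EGF"] <- 10; p["bath_NRG1"] <- 5
  y0 <- skbr3VitroSS()
  tr <- qspHER2:::.solve(y0, seq(0, 48, by = 2), p)
  tot <- receptorTotals(tr)
  for (r in colnames(tot))
    expect_lt(max(abs(tot[, r] / tot[1, r] - 1)), 1e-6)
})

test_that("zero stimulus leaves all readouts flat", {
  net <- skbr3Vitro()
  tr <- simulateTimecourse(net, skbr3VitroSS(), stimulus(), 24)
  for (nm in c("pEGFR", "pHER2", "pHER3", "pAKT", "pERK")) {
    ro <- readout(tr, nm)
    expect_lt(diff(range(ro)) / max(ro[1], 1e-9), 1e-4)
  }
})

test_that("EGF induces a fast rise in pEGFR that then relaxes", {
  net <- skbr3Vitro()
  tr <- simulateTimecourse(net, skbr3VitroSS(),
                           applyLigand(stimulus(), "EGF", 100), 24)
  pe <- readout(tr, "pEGFR")
  tpk <- trajTimes(tr)[which.max(pe)]
  expect_gt(max(pe), 10 * (pe[1] + 1))
  expect_lt(tpk, 2)                       # activation within minutes
  expect_lt(pe[length(pe)], 0.8 * max(pe))  # partial relaxation by 24 h
})
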