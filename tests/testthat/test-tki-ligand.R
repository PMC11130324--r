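test_that("lapatinib 100 nM alone shuts the pathway down within 1 h", {
  base_akt <- skbr3VitroSS()[["pAKT"]]
  base_erk <- skbr3VitroSS()[["pERK"]]
  akt <- readoutAt(stimulus(lapatinib = 100), "pAKT", 1)
  erk <- readoutAt(stimulus(lapatinib = 100), "pERK", 1)
  expect_lt(akt / base_akt, 0.05)
  expect_lt(erk / base_erk, 0.05)
})

test_that("zero drug concentration leaves the trajectory untouched", {
  net <- skbr3Vitro()
  ss <- skbr3VitroSS()
  tr0 <- simulateTimecourse(net, ss, stimulus(), 8)
  tr1 <- simulateTimecourse(net, ss, stimulus(lapatinib = 0,
                                              pyrotinib = 0), 8)
  expect_equal(trajStates(tr0), trajStates(tr1))
})

test_that("NRG1 sustains signaling even at 1000 nM lapatinib", {
  base_akt <- skbr3VitroSS()[["pAKT"]]
  base_erk <- skbr3VitroSS()[["pERK"]]
  stim <- applyLigand(stimulus(lapatinib = 1000), "NRG1", 50)
  expect_gt(readoutAt(stim, "pAKT", 1) / base_akt, 0.2)
  expect_gt(readoutAt(stim, "pERK", 1) / base_erk, 0.2)
})

test_that("steady-state pERK and pAKT are non-increasing in TKI dose", {
  doses <- 10^seq(-1, 3, length.out = 10)
  for (drug in c("lapatinib", "pyrotinib")) {
    erk <- vapply(doses, function(d) {
      s <- stimulus(); s[[drug]] <- d
      endReadout(s, "pERK", 72)
    }, 0)
    akt <- vapply(doses, function(d) {
      s <- stimulus(); s[[drug]] <- d
      endReadout(s, "pAKT", 72)
    }, 0)
    expect_true(all(diff(erk) <= 1e-9), info = drug)
    expect_true(all(diff(akt) <= 1e-9), info = drug)
  }
})

test_that("pyrotinib downregulates total HER2 and induces HER3", {
  h2 <- endReadout(stimulus(pyrotinib = 20), "HER2_total", 24)
  h3 <- endReadout(stimulus(pyrotinib = 20), "HER3_total", 24)
  h2c <- endReadout(stimulus(), "HER2_total", 24)
  h3c <- endReadout(stimulus(), "HER3_total", 24)
  expect_lt(h2, h2c)
  expect_gte(h3, h3c)
})

test_that("NRG1 downregulates total HER3; lapatinib induces it (FOXO)", {
  h3c <- endReadout(stimulus(), "HER3_total", 24)
  expect_lt(endReadout(applyLigand(stimulus(), "NRG1", 50),
                       "HER3_total", 24), h3c)
  expect_gt(endReadout(stimulus(lapatinib = 100), "HER3_total", 24), h3c)
})

test_that("lower pAKT raises the HER3 synthesis flux (FOXO feedback
           direction)", {
  net <- skbr3Vitro()
  p <- net@params
  flux <- function(pakt)
    p[["ksyn3"]] * (1 + p[["fb_fold"]] * p[["km_fb"]] /
                      (p[["km_fb"]] + pakt))
  base <- skbr3VitroSS()[["pAKT"]]
  lower <- readoutAt(stimulus(lapatinib = 100), "pAKT", 4)
  expect_lt(lower, base)
  expect_gt(flux(lower), flux(base))
})

test_that("covalent pyrotinib occupancy persists after washout while
           lapatinib occupancy is instantaneous", {
  net <- skbr3Vitro()
  ss <- skbr3VitroSS()
  tr <- simulateTimecourse(net, ss, stimulus(pyrotinib = 40), 6)
  st <- trajStates(tr)[nrow(trajStates(tr)), ]
  expect_gt(st[["thP2"]], 0.5)
  ## continue without drug: occupancy decays only at the slow recovery rate
  tr2 <- simulateTimecourse(net, st, stimulus(), 2)
  end <- trajStates(tr2)[nrow(trajStates(tr2)), "thP2"]
  expect_gt(end, 0.8 * st[["thP2"]])
})

test_that("ligand dosing converts ng/mL to nM via molecular weight", {
  expect_equal(ligandToNM("EGF", 100), 100 / 6.2)
  expect_equal(ligandToNM("NRG1", 50), 50 / 7.5)
  expect_equal(applyLigand(stimulus(), "NRG1", 0)$NRG1, 0)
  expect_error(applyLigand(stimulus(), "TGFa", 10))
})
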