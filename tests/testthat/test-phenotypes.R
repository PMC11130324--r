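test_that("phenotype presets are well formed", {
  sens <- makePhenotype("sensitive")
  expect_length(sens@multipliers, 0)
  expect_length(sens@absolutes, 0)
  expect_error(makePhenotype("mystery"), "presets")
  ## overrides reference existing parameters only
  tr <- makePhenotype("tdm1_resistant")
  expect_true(all(names(tr@multipliers) %in% names(paramTemplate())))
  expect_equal(unname(tr@multipliers["kout_PL"]), 50)
})

test_that("raising DM1 efflux erodes T-DM1 efficacy monotonically", {
  net <- skbr3Vivo()
  rg <- regimen(regimenArm("tdm1", 30, "q3w"))
  tgis <- vapply(c(1, 5, 20, 100), function(mult) {
    app <- applyPhenotype(net, makePhenotype("tdm1_resistant",
                                             multipliers = c(kout_PL = mult)))
    tgiAtDay(rg, network = app$network, stim = app$stim)
  }, 0)
  expect_true(all(diff(tgis) <= 1))
  expect_gt(tgis[1] - tgis[4], 30)
})

test_that("the T-DM1-resistant phenotype stays responsive to T-DXd and
           TKIs", {
  net <- skbr3Vivo()
  app <- applyPhenotype(net, makePhenotype("tdm1_resistant"))
  run <- function(rg) tgiAtDay(rg, network = app$network, stim = app$stim)
  expect_lt(run(regimen(regimenArm("tdm1", 30, "q3w"))), 25)
  expect_gt(run(regimen(regimenArm("tdxd", 10, "q3w"))), 50)
  expect_gt(run(regimen(regimenArm("pyrotinib", 30, "qd"))), 80)
})

test_that("HER3 blockade restores TKI efficacy under NRG1
           overexpression", {
  net <- skbr3Vivo()
  lap <- regimen(regimenArm("lapatinib", 100, "qd"))
  base <- tgiAtDay(lap, network = net)
  nrg <- applyPhenotype(net, makePhenotype("nrg1_over"))
  lost <- tgiAtDay(lap, network = nrg$network, stim = nrg$stim)
  resc <- applyPhenotype(net, makePhenotype("nrg1_over"),
                         makePhenotype("her3_mab"))
  restored <- tgiAtDay(lap, network = resc$network, stim = resc$stim)
  expect_lt(lost, base - 50)
  expect_gt(restored, base - 10)   # within 10 points of the NRG1-free TGI
})

test_that("PI3K inhibition synergizes with lapatinib in the
           PIK3CA-dependent phenotype", {
  net <- skbr3Vivo()
  lap <- regimen(regimenArm("lapatinib", 100, "qd"))
  pik <- applyPhenotype(net, makePhenotype("pik3ca_dependent"))
  ctl <- runXenograft(pik$network, regimen(), 21, stim0 = pik$stim)
  lapOnly <- computeTGI(runXenograft(pik$network, lap, 21,
                                     stim0 = pik$stim), ctl, 20)
  both <- applyPhenotype(net, makePhenotype("pik3ca_dependent"),
                         makePhenotype("pi3k_inhibited"))
  pi3kOnly <- computeTGI(runXenograft(both$network, regimen(), 21,
                                      stim0 = both$stim), ctl, 20)
  combo <- computeTGI(runXenograft(both$network, lap, 21,
                                   stim0 = both$stim), ctl, 20)
  expect_gt(combo, lapOnly)
  expect_gt(combo, pi3kOnly)
})

test_that("TGI of HER2-targeted therapy falls with HER2 expression", {
  levels <- c("3+", "2+", "1+")
  tgis <- sapply(levels, function(lvl) {
    net <- buildNetwork(ihcPreset(lvl, inVivo = TRUE), inVitro = FALSE)
    c(tdm1 = tgiAtDay(regimen(regimenArm("tdm1", 30, "q3w")),
                      network = net),
      lapatinib = tgiAtDay(regimen(regimenArm("lapatinib", 100, "qd")),
                           network = net),
      pyrotinib = tgiAtDay(regimen(regimenArm("pyrotinib", 30, "qd")),
                           network = net))
  })
  for (drug in rownames(tgis))
    expect_true(all(diff(tgis[drug, ]) <= 1), info = drug)
})

test_that("the regimen grid is stable under arm permutation", {
  regs <- regimenPresets()[c("lapatinib", "tdm1", "pyrotinib+tdm1")]
  g1 <- phenotypeRegimenGrid(list("sensitive"), regs)
  g2 <- phenotypeRegimenGrid(list("sensitive"), rev(regs))
  expect_equal(g1[, names(regs)], g2[, names(regs)])
})

test_that("acquired-resistance hook: potency decay lets tumors escape
           repeated cycles", {
  net <- skbr3Vivo()
  rg <- regimen(regimenArm("tdm1", 10, "q3w"))
  stable <- simulateAcquiredResistance(net, rg, cycles = 3, decay = 0)
  escaped <- simulateAcquiredResistance(net, rg, cycles = 3, decay = 1.5)
  expect_gt(escaped$volume[nrow(escaped)],
            stable$volume[nrow(stable)])
})
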