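test_that("network respects the structural budget and dimer inventory", {
  net <- skbr3Vitro()
  expect_lte(nrow(net@species), 60)
  expect_lte(reactionCount(net), 80)
  rx <- vapply(net@reactions, `[[`, "", "name")
  ## exactly the five dimerization routes; HER3 homodimers absent
  dims <- grep("^dimerization_", rx, value = TRUE)
  expect_setequal(dims, c("dimerization_egfr_her2", "dimerization_her2_her2",
                          "dimerization_her2_her3",
                          "dimerization_nrg1her3_her2",
                          "dimerization_nrg1her4_her2"))
  expect_false(any(grepl("her3_her3", rx)))
  ## every rate-law tag is one of the two allowed families
  expect_true(all(vapply(net@reactions, `[[`, "", "law") %in%
                    c("mass_action", "hill")))
})

test_that("cell line presets carry the measured receptor numbers", {
  sk <- cellLineConfig("SKBR3")
  expect_identical(unname(receptorCounts(sk)[c("EGFR", "HER2", "HER3",
                                               "HER4")]),
                   c(150000, 1.5e6, 40000, 2000))
  net <- buildNetwork(sk)
  ini <- net@species$initial
  names(ini) <- net@species$name
  expect_equal(unname(ini["E2"]), 1.5e6)
  expect_equal(unname(buildNetwork(cellLineConfig("NCI-N87"))@species$initial[2]),
               0.5e6)
  expect_equal(unname(receptorCounts(ihcPreset("1+"))["HER2"]), 0.1e6)
})

test_that("configuration errors are caught", {
  expect_error(cellLineConfig("custom",
                              receptors = c(EGFR = 1, HER2 = 1, HER5 = 1)),
               "unknown receptor")
  expect_error(buildNetwork(drugs = "gefitinib"), "unknown drug")
  expect_error(signalingParams(k8on = -1), "non-negative")
  expect_error(signalingParams(n_PI3K = 0.5), "Hill exponents")
  expect_error(growthDeathParams(umax = 0.01, dmax = 0.5),
               "umax > dmax")
})

test_that("compiled right-hand side equals the naive per-reaction
           interpreter at random states", {
  net <- skbr3Vitro()
  p <- net@params
  p["bath_EGF"] <- 8; p["bath_NRG1"] <- 4; p["bath_lap"] <- 30
  p["bath_pyr"] <- 10; p["bath_FU"] <- 2000
  set.seed(42)
  for (i in 1:100) {
    y <- stateTemplate()
    y[] <- abs(rnorm(length(y), 50, 200))
    y[c("PI3K", "pPI3K", "AKT", "pAKT", "RAF", "pRAF", "ERK", "pERK",
        "thP1", "thP2", "thP4")] <- runif(11)
    dC <- qspHER2:::.evalRHS(y, p)
    dI <- interpretRHS(net, y, p)
    expect_equal(unname(dC), unname(dI), tolerance = 1e-10)
  }
})

test_that("stoichiometry conserves receptor monomers for conserving
           reactions", {
  net <- skbr3Vitro()
  nm <- net@species$name
  ## monomer-equivalent weights per receptor
  w <- list(
    EGFR = c(E1 = 1, LE1 = 1, D12 = 1, pD12 = 1),
    HER2 = c(E2 = 1, D12 = 1, pD12 = 1, D22 = 2, pD22 = 2, D23 = 1,
             pD23 = 1, D32 = 1, pD32 = 1, D42 = 1, pD42 = 1, CPX1 = 1,
             INT1 = 1, CPX2 = 1, INT2 = 1),
    HER3 = c(E3 = 1, NE3 = 1, D23 = 1, pD23 = 1, D32 = 1, pD32 = 1),
    HER4 = c(E4 = 1, NE4 = 1, D42 = 1, pD42 = 1))
  for (j in seq_along(net@reactions)) {
    rx <- net@reactions[[j]]
    if (!rx$conserves) next
    for (r in names(w)) {
      wt <- rep(0, length(nm)); names(wt) <- nm
      wt[names(w[[r]])] <- w[[r]]
      expect_equal(sum(wt * net@stoichiometry[, j]), 0,
                   info = paste(rx$name, r))
    }
  }
})

test_that("a receptor-free configuration produces no phospho-signal", {
  cl <- cellLineConfig("null",
                       receptors = c(EGFR = 0, HER2 = 0, HER3 = 0,
                                     HER4 = 0),
                       growth = growthDeathParams())
  net <- buildNetwork(cl)
  ss <- initializeSteadyState(net, maxT = 4000)
  expect_equal(unname(ss[c("pD12", "pD22", "pD23", "pD32", "pD42")]),
               rep(0, 5))
  tr <- simulateTimecourse(net, ss, applyLigand(stimulus(), "EGF", 100), 24)
  expect_true(all(readout(tr, "pEGFR") == 0))
})

test_that("SBML export is structurally complete and well formed", {
  net <- skbr3Vitro()
  f <- tempfile(fileext = ".xml")
  exportSBML(net, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  sp <- xml2::xml_find_all(doc, ".//sbml:species", ns)
  expect_length(sp, nrow(net@species))
  rxns <- xml2::xml_find_all(doc, ".//sbml:reaction", ns)
  expect_length(rxns, reactionCount(net))
  expect_setequal(xml2::xml_attr(sp, "id"), speciesNames(net))
  unlink(f)
})

test_that("trajectory export is tidy long-format text", {
  net <- skbr3Vitro()
  tr <- simulateTimecourse(net, skbr3VitroSS(), stimulus(), 2, dt = 1)
  f <- tempfile(fileext = ".tsv")
  writeTrajectory(tr, f, species = c("E2", "pAKT"))
  tab <- read.delim(f)
  expect_identical(names(tab), c("time", "species", "value", "unit"))
  expect_setequal(unique(tab$species), c("E2", "pAKT"))
  expect_equal(nrow(tab), 2 * length(trajTimes(tr)))
  unlink(f)
})
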