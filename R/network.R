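## Symbolic reaction network: the definitional form of the ODE system.
## Each reaction carries reactants/products (via a sparse stoichiometry
## record), a rate-law tag and a rate closure. A naive per-reaction
## interpreter over this object (interpretRHS) is the reference
## implementation against which the compiled right-hand side is verified.

## algebraic quantities shared by several rate laws
.modelAux <- function(y, p) {
  C_lap <- p[["bath_lap"]] +
    p[["f_pk"]] * p[["Kp_lap"]] * (y[["CLAPC"]] / p[["lap_Vc"]]) * 1721
  C_pyr <- p[["bath_pyr"]] +
    p[["f_pk"]] * p[["Kp_pyr"]] * (y[["CPYRC"]] / p[["pyr_Vc"]]) * 1715
  C_FU <- p[["bath_FU"]] +
    p[["f_pk"]] * p[["Kp_FU"]] * (y[["AFU"]] / p[["cap_Vmet"]]) * 7688
  thL <- C_lap / (p[["Kd_lap"]] + C_lap)
  thLp <- C_lap / (p[["Kd_lap"]] * p[["prot_lap"]] + C_lap)
  comb <- function(a, b) a + b - a * b
  th1 <- comb(thL, y[["thP1"]]); th2 <- comb(thL, y[["thP2"]])
  th1p <- comb(thLp, y[["thP1"]]); th2p <- comb(thLp, y[["thP2"]])
  th4p <- y[["thP4"]]
  list(C_lap = C_lap, C_pyr = C_pyr, C_FU = C_FU, thL = thL,
       act12 = 1 - th1p * th2p, act22 = 1 - th2 * th2, act23 = 1 - th2,
       act32 = 1 - th2p, act42 = 1 - th4p * th2p,
       S_pi3k = p[["w_her3"]] * (y[["pD32"]] + y[["pD42"]]) +
         p[["w_her3_basal"]] * y[["pD23"]] +
         y[["pD12"]] + p[["w22"]] * 2 * y[["pD22"]],
       fbm = 1 + p[["fb_fold"]] * p[["km_fb"]] /
         (p[["km_fb"]] + y[["pAKT"]]))
}

.rxn <- function(name, law, stoich, rate, conserves = TRUE) {
  list(name = name, law = law, stoich = stoich, rate = rate,
       conserves = conserves)
}

.cellReactions <- function() {
  h <- function(x, km, n) if (x <= 0) 0 else x^n / (km^n + x^n)
  r <- list(
    .rxn("egf_binding", "mass_action", c(E1 = -1, LE1 = 1),
         function(y, p, a)
           p[["kEGFon"]] * p[["bath_EGF"]] * y[["E1"]] -
           p[["kEGFoff"]] * y[["LE1"]]),
    .rxn("nrg1_her3_binding", "mass_action", c(E3 = -1, NE3 = 1),
         function(y, p, a)
           p[["k8on"]] * p[["bath_NRG1"]] * y[["E3"]] -
           p[["k8off"]] * y[["NE3"]]),
    .rxn("nrg1_her4_binding", "mass_action", c(E4 = -1, NE4 = 1),
         function(y, p, a)
           p[["kNRG4on"]] * p[["bath_NRG1"]] * y[["E4"]] -
           p[["kNRG4off"]] * y[["NE4"]]),
    .rxn("dimerization_egfr_her2", "mass_action",
         c(LE1 = -1, E2 = -1, D12 = 1),
         function(y, p, a)
           p[["kon12"]] * y[["LE1"]] * y[["E2"]] - p[["koff12"]] * y[["D12"]]),
    .rxn("dimerization_her2_her2", "mass_action", c(E2 = -2, D22 = 1),
         function(y, p, a)
           p[["kon22"]] * y[["E2"]]^2 - p[["koff22"]] * y[["D22"]]),
    .rxn("dimerization_her2_her3", "mass_action",
         c(E2 = -1, E3 = -1, D23 = 1),
         function(y, p, a)
           p[["kon23"]] * y[["E2"]] * y[["E3"]] - p[["koff23"]] * y[["D23"]]),
    .rxn("dimerization_nrg1her3_her2", "mass_action",
         c(NE3 = -1, E2 = -1, D32 = 1),
         function(y, p, a)
           p[["kon32"]] * y[["NE3"]] * y[["E2"]] - p[["koff32"]] * y[["D32"]]),
    .rxn("dimerization_nrg1her4_her2", "mass_action",
         c(NE4 = -1, E2 = -1, D42 = 1),
         function(y, p, a)
           p[["kon42"]] * y[["NE4"]] * y[["E2"]] - p[["koff42"]] * y[["D42"]]),
    .rxn("phospho_D12", "mass_action", c(D12 = -1, pD12 = 1),
         function(y, p, a)
           p[["kphos"]] * a$act12 * y[["D12"]] - p[["kdeph"]] * y[["pD12"]]),
    .rxn("phospho_D22", "mass_action", c(D22 = -1, pD22 = 1),
         function(y, p, a)
           p[["kphos"]] * a$act22 * y[["D22"]] - p[["kdeph"]] * y[["pD22"]]),
    .rxn("phospho_D23", "mass_action", c(D23 = -1, pD23 = 1),
         function(y, p, a)
           p[["kphos"]] * a$act23 * y[["D23"]] - p[["kdeph"]] * y[["pD23"]]),
    .rxn("phospho_D32", "mass_action", c(D32 = -1, pD32 = 1),
         function(y, p, a)
           p[["kphos"]] * a$act32 * y[["D32"]] - p[["kdeph"]] * y[["pD32"]]),
    .rxn("phospho_D42", "mass_action", c(D42 = -1, pD42 = 1),
         function(y, p, a)
           p[["kphos"]] * a$act42 * y[["D42"]] - p[["kdeph"]] * y[["pD42"]]),
    .rxn("synthesis_EGFR", "mass_action", c(E1 = 1),
         function(y, p, a) p[["f_turnover"]] * p[["ksyn1"]],
         conserves = FALSE),
    .rxn("synthesis_HER2", "mass_action", c(E2 = 1),
         function(y, p, a) p[["f_turnover"]] * p[["ksyn2"]],
         conserves = FALSE),
    .rxn("synthesis_HER3_foxo", "hill", c(E3 = 1),
         function(y, p, a) p[["f_turnover"]] * p[["ksyn3"]] * a$fbm,
         conserves = FALSE),
    .rxn("synthesis_HER4", "mass_action", c(E4 = 1),
         function(y, p, a) p[["f_turnover"]] * p[["ksyn4"]],
         conserves = FALSE),
    .rxn("degradation_EGFR", "mass_action", c(E1 = -1),
         function(y, p, a)
           p[["f_turnover"]] * p[["kdeg1"]] *
           (1 + (p[["degfold_lap"]] - 1) * a$thL +
              (p[["degfold_pyr"]] - 1) * y[["thP1"]]) * y[["E1"]],
         conserves = FALSE),
    .rxn("degradation_HER2", "mass_action", c(E2 = -1),
         function(y, p, a)
           p[["f_turnover"]] * p[["kdeg2"]] *
           (1 + (p[["degfold_lap"]] - 1) * a$thL +
              (p[["degfold_pyr"]] - 1) * y[["thP2"]]) * y[["E2"]],
         conserves = FALSE),
    .rxn("degradation_HER3", "mass_action", c(E3 = -1),
         function(y, p, a)
           p[["f_turnover"]] * p[["kdeg3"]] * y[["E3"]],
         conserves = FALSE),
    .rxn("degradation_HER4", "mass_action", c(E4 = -1),
         function(y, p, a)
           p[["f_turnover"]] * p[["kdeg4"]] *
           (1 + (p[["degfold_pyr"]] - 1) * y[["thP4"]]) * y[["E4"]],
         conserves = FALSE)
  )
  ## ligand-induced internalization of ligand-bound species
  for (sp in c("LE1", "NE3", "NE4", "D12", "pD12", "D32", "pD32", "D42",
               "pD42")) {
    st <- -1; names(st) <- sp
    local({
      spl <- sp
      r[[length(r) + 1L]] <<- .rxn(paste0("internalization_", spl),
        "mass_action", st,
        function(y, p, a) p[["f_turnover"]] * p[["kint_lig"]] * y[[spl]],
        conserves = FALSE)
    })
  }
  r <- c(r, list(
    .rxn("pi3k_activation", "hill", c(PI3K = -1, pPI3K = 1),
         function(y, p, a)
           p[["kon_PI3K"]] * h(a$S_pi3k, p[["km_PI3K"]], p[["n_PI3K"]]) *
           y[["PI3K"]] - p[["koff_PI3K"]] * y[["pPI3K"]]),
    .rxn("akt_activation", "hill", c(AKT = -1, pAKT = 1),
         function(y, p, a)
           p[["kon_AKT"]] * h(y[["pPI3K"]], p[["km_AKTact"]],
                              p[["n_AKTact"]]) * y[["AKT"]] -
           p[["koff_AKT"]] * y[["pAKT"]]),
    .rxn("raf_activation", "hill", c(RAF = -1, pRAF = 1),
         function(y, p, a)
           p[["kon_Raf"]] * p[["w7"]] * h(a$S_pi3k, p[["km7"]], p[["n7"]]) *
           y[["RAF"]] - p[["koff_Raf"]] * y[["pRAF"]]),
    .rxn("erk_activation", "hill", c(ERK = -1, pERK = 1),
         function(y, p, a)
           p[["kon_ERK"]] * p[["w8"]] * h(y[["pRAF"]], p[["km8"]],
                                          p[["n8"]]) * y[["ERK"]] -
           p[["koff_ERK"]] * y[["pERK"]]),
    .rxn("tumor_growth", "hill", c(NCELL = 1),
         function(y, p, a) {
           S <- (p[["w11"]] * h(y[["pERK"]], p[["km11"]], p[["n11"]]) +
                 p[["wAKT"]] * h(y[["pAKT"]], p[["km_AKTg"]],
                                 p[["n_AKTg"]]) +
                 p[["w_basal"]] +
                 p[["w_btk"]] * h(p[["bath_NRG1"]], p[["km_btk"]], 1)) /
             (p[["w11"]] + p[["wAKT"]] + p[["w_basal"]] + p[["w_btk"]])
           gfac <- if (p[["f_invitro"]] > 0.5) 1 else
             1 - (y[["NCELL"]] / p[["cells_per_mm3"]]) / p[["Vmax"]]
           (p[["umax"]] / 24) * h(S, p[["km13"]], p[["n13"]]) * gfac *
             y[["NCELL"]]
         }, conserves = FALSE),
    .rxn("tumor_death", "hill", c(NCELL = -1),
         function(y, p, a)
           (p[["dmax"]] / 24) *
           (1 + p[["w14_dm1"]] * h(y[["PIN1"]], p[["km14_dm1"]],
                                   p[["n14_dm1"]]) +
              p[["w14_dxd"]] * h(y[["PIN2"]], p[["km14_dxd"]],
                                 p[["n14_dxd"]]) +
              p[["w15"]] * h(a$C_FU, p[["km10"]], p[["n10"]])) *
           y[["NCELL"]],
         conserves = FALSE)
  ))
  r
}

.drugReactions <- function(drugs) {
  r <- list()
  if ("pyrotinib" %in% drugs) {
    for (tg in c("1", "2", "4")) {
      st <- 1; names(st) <- paste0("thP", tg)
      local({
        tgl <- tg
        r[[length(r) + 1L]] <<- .rxn(paste0("pyrotinib_inactivation_", tgl),
          "mass_action", st,
          function(y, p, a)
            p[["kinact_pyr"]] * a$C_pyr * (1 - y[[paste0("thP", tgl)]]) -
            p[["krec_pyr"]] * y[[paste0("thP", tgl)]],
          conserves = FALSE)
      })
    }
  }
  adcSpecs <- list(
    tdm1 = list(sfx = "1", kon = "konA1", koff = "koffA1",
                kint = "kint_ADC1", kdeg = "kdeg_ADC_2_1", dar = "DAR1",
                ktu = "ktu1", kel = "kelim_tu1"),
    tdxd = list(sfx = "2", kon = "konA2", koff = "koffA2",
                kint = "kint_ADC2", kdeg = "kdeg_ADC_2_2", dar = "DAR2",
                ktu = "ktu2", kel = "kelim_tu2"))
  for (dg in intersect(names(adcSpecs), drugs)) {
    s <- adcSpecs[[dg]]
    adc <- paste0("ADC", s$sfx); cpx <- paste0("CPX", s$sfx)
    int <- paste0("INT", s$sfx); pin <- paste0("PIN", s$sfx)
    pex <- paste0("PEX", s$sfx)
    st1 <- c(-1, 1); names(st1) <- c("E2", cpx)
    st2 <- c(-1, 1); names(st2) <- c(cpx, int)
    ## binding does not deplete the extracellular nM pool (documented
    ## bath/tumor-reservoir approximation)
    r[[length(r) + 1L]] <- local({
      sl <- s; adcl <- adc; cpxl <- cpx
      .rxn(paste0(dg, "_her2_binding"), "mass_action", st1,
           function(y, p, a)
             p[[sl$kon]] * y[[adcl]] * y[["E2"]] - p[[sl$koff]] * y[[cpxl]])
    })
    r[[length(r) + 1L]] <- local({
      sl <- s; cpxl <- cpx
      .rxn(paste0(dg, "_internalization"), "mass_action", st2,
           function(y, p, a) p[[sl$kint]] * y[[cpxl]])
    })
    st3 <- c(-1, NA); names(st3) <- c(int, pin)
    r[[length(r) + 1L]] <- local({
      sl <- s; intl <- int; p0 <- paramTemplate()
      st3[2] <- p0[[sl$dar]]
      .rxn(paste0(dg, "_lysosomal_processing"), "mass_action", st3,
           function(y, p, a)
             p[["f_turnover"]] * p[[sl$kdeg]] * y[[intl]],
           conserves = FALSE)
    })
    stR <- -1; names(stR) <- int
    r[[length(r) + 1L]] <- local({
      intl <- int; krp <- paste0("krec_ADC", s$sfx)
      .rxn(paste0(dg, "_recycling"), "mass_action", stR,
           function(y, p, a)
             p[["f_turnover"]] * p[[krp]] * y[[intl]],
           conserves = FALSE)
    })
    if (dg == "tdm1") {
      st4 <- c(-1, NA); names(st4) <- c(pin, pex)
      r[[length(r) + 1L]] <- local({
        pinl <- pin; p0 <- paramTemplate()
        st4[2] <- p0[["cellconv"]]
        .rxn("dm1_efflux", "mass_action", st4,
             function(y, p, a) p[["kout_PL"]] * y[[pinl]],
             conserves = FALSE)
      })
    } else {
      st4 <- c(-1, NA); names(st4) <- c(pin, pex)
      r[[length(r) + 1L]] <- local({
        pinl <- pin; pexl <- pex; p0 <- paramTemplate()
        st4[2] <- p0[["cellconv"]]
        .rxn("dxd_membrane_permeation", "mass_action", st4,
             function(y, p, a)
               p[["kper_PL"]] * (y[[pinl]] - y[[pexl]] * p[["volfac"]]),
             conserves = FALSE)
      })
    }
    st5 <- -1; names(st5) <- pex
    r[[length(r) + 1L]] <- local({
      pexl <- pex; kelp <- paste0("kelim_pex", s$sfx)
      .rxn(paste0(dg, "_extracellular_payload_elim"), "mass_action", st5,
           function(y, p, a) p[[kelp]] * y[[pexl]],
           conserves = FALSE)
    })
    st6 <- 1; names(st6) <- adc
    r[[length(r) + 1L]] <- local({
      sl <- s; a1c <- paste0("A", s$sfx, "C")
      .rxn(paste0(dg, "_tumor_entry"), "mass_action", st6,
           function(y, p, a) p[["f_pk"]] * p[[sl$ktu]] * y[[a1c]],
           conserves = FALSE)
    })
    st7 <- -1; names(st7) <- adc
    r[[length(r) + 1L]] <- local({
      sl <- s; adcl <- adc
      .rxn(paste0(dg, "_tumor_elim"), "mass_action", st7,
           function(y, p, a) p[["f_pk"]] * p[[sl$kel]] * y[[adcl]],
           conserves = FALSE)
    })
  }
  r
}

.pkReactions <- function(drugs) {
  r <- list()
  two <- function(drug, pre, gut, cen, per) {
    ka <- paste0(pre, "_ka"); CL <- paste0(pre, "_CL")
    Vc <- paste0(pre, "_Vc"); Q <- paste0(pre, "_Q")
    Vp <- paste0(pre, "_Vp")
    st1 <- c(-1, 1); names(st1) <- c(gut, cen)
    st2 <- -1; names(st2) <- cen
    st3 <- c(-1, 1); names(st3) <- c(cen, per)
    list(
      .rxn(paste0(drug, "_absorption"), "mass_action", st1,
           function(y, p, a) p[[ka]] * y[[gut]], conserves = FALSE),
      .rxn(paste0(drug, "_clearance"), "mass_action", st2,
           function(y, p, a) p[[CL]] * y[[cen]] / p[[Vc]],
           conserves = FALSE),
      .rxn(paste0(drug, "_distribution"), "mass_action", st3,
           function(y, p, a)
             p[[Q]] * (y[[cen]] / p[[Vc]] - y[[per]] / p[[Vp]]),
           conserves = FALSE))
  }
  adcPk <- function(drug, pre, cen, per, plc, plp) {
    CL <- paste0(pre, "_CL"); Vc <- paste0(pre, "_Vc")
    Q <- paste0(pre, "_Q"); Vp <- paste0(pre, "_Vp")
    krel <- paste0(pre, "_krel"); CLpl <- paste0(pre, "_CLpl")
    Vcpl <- paste0(pre, "_Vcpl"); Qpl <- paste0(pre, "_Qpl")
    Vppl <- paste0(pre, "_Vppl")
    st1 <- -1; names(st1) <- cen
    st2 <- c(-1, 1); names(st2) <- c(cen, per)
    st3 <- c(-1, 1); names(st3) <- c(cen, plc)
    st4 <- -1; names(st4) <- plc
    st5 <- c(-1, 1); names(st5) <- c(plc, plp)
    list(
      .rxn(paste0(drug, "_clearance"), "mass_action", st1,
           function(y, p, a) p[[CL]] * y[[cen]] / p[[Vc]],
           conserves = FALSE),
      .rxn(paste0(drug, "_distribution"), "mass_action", st2,
           function(y, p, a)
             p[[Q]] * (y[[cen]] / p[[Vc]] - y[[per]] / p[[Vp]]),
           conserves = FALSE),
      .rxn(paste0(drug, "_deconjugation"), "mass_action", st3,
           function(y, p, a) p[[krel]] * y[[cen]], conserves = FALSE),
      .rxn(paste0(drug, "_payload_clearance"), "mass_action", st4,
           function(y, p, a) p[[CLpl]] * y[[plc]] / p[[Vcpl]],
           conserves = FALSE),
      .rxn(paste0(drug, "_payload_distribution"), "mass_action", st5,
           function(y, p, a)
             p[[Qpl]] * (y[[plc]] / p[[Vcpl]] - y[[plp]] / p[[Vppl]]),
           conserves = FALSE))
  }
  if ("lapatinib" %in% drugs)
    r <- c(r, two("lapatinib", "lap", "GLAP", "CLAPC", "CLAPP"))
  if ("pyrotinib" %in% drugs)
    r <- c(r, two("pyrotinib", "pyr", "GPYR", "CPYRC", "CPYRP"))
  if ("tdm1" %in% drugs)
    r <- c(r, adcPk("tdm1", "tdm1", "A1C", "A1P", "PL1C", "PL1P"))
  if ("tdxd" %in% drugs)
    r <- c(r, adcPk("tdxd", "tdxd", "A2C", "A2P", "PL2C", "PL2P"))
  if ("capecitabine" %in% drugs) {
    st1 <- c(GCAP = -1, ACAP = 1)
    st2 <- c(ACAP = -1, DFCR = 1)
    st3 <- c(DFCR = -1, DFUR = 1)
    st4 <- c(DFUR = -1, AFU = 1)
    mk <- function(name, st, f) .rxn(name, "mass_action", st, f,
                                     conserves = FALSE)
    r <- c(r, list(
      mk("capecitabine_absorption", st1,
         function(y, p, a) p[["cap_ka"]] * y[["GCAP"]]),
      mk("capecitabine_to_dfcr", st2,
         function(y, p, a) p[["cap_k1"]] * y[["ACAP"]]),
      mk("dfcr_to_dfur", st3,
         function(y, p, a) p[["cap_k2"]] * y[["DFCR"]]),
      mk("dfur_to_fu", st4,
         function(y, p, a) p[["cap_k3"]] * y[["DFUR"]]),
      mk("capecitabine_clearance", c(ACAP = -1),
         function(y, p, a) p[["cap_CL"]] * y[["ACAP"]] / p[["cap_V"]]),
      mk("dfcr_clearance", c(DFCR = -1),
         function(y, p, a) p[["cap_CLdfcr"]] * y[["DFCR"]] / p[["cap_Vmet"]]),
      mk("dfur_clearance", c(DFUR = -1),
         function(y, p, a) p[["cap_CLdfur"]] * y[["DFUR"]] / p[["cap_Vmet"]]),
      mk("fu_clearance", c(AFU = -1),
         function(y, p, a) p[["cap_CLfu"]] * y[["AFU"]] / p[["cap_Vmet"]])))
  }
  r
}

.speciesUnits <- function() {
  nm <- names(stateTemplate())
  unit <- rep("molecules/cell", length(nm))
  names(unit) <- nm
  unit[c("PI3K", "pPI3K", "AKT", "pAKT", "RAF", "pRAF", "ERK", "pERK",
         "thP1", "thP2", "thP4")] <- "fraction"
  unit[c("ADC1", "ADC2", "PEX1", "PEX2")] <- "nM"
  unit["NCELL"] <- "cells"
  unit[c("GLAP", "CLAPC", "CLAPP", "GPYR", "CPYRC", "CPYRP", "A1C", "A1P",
         "PL1C", "PL1P", "A2C", "A2P", "PL2C", "PL2P", "GCAP", "ACAP",
         "DFCR", "DFUR", "AFU")] <- "mg"
  unit
}

#' Build the full reaction network
#'
#' Assembles the ErbB signaling network, tumor growth/death law, the
#' mechanisms of the requested drugs, and their PK modules into a
#' \code{\linkS4class{ReactionNetwork}}. The dimer inventory is exactly
#' \{EGF:EGFR-HER2, HER2-HER2, HER2-HER3 (ligand-independent),
#' NRG1:HER3-HER2, NRG1:HER4-HER2\}; HER3 homodimers are absent (HER3 is
#' kinase-dead).
#'
#' @param cellLine a \code{\link{cellLineConfig}}.
#' @param signaling signaling parameter list (\code{\link{signalingParams}}).
#' @param drugs character vector of drugs to wire (any of "lapatinib",
#'   "pyrotinib", "tdm1", "tdxd", "capecitabine"); may be empty.
#' @param mechanisms optional list of \code{\link{drugMechanism}} records
#'   overriding per-drug defaults.
#' @param pk optional list of \code{\link{pkParams}} records.
#' @param inVitro logical: constant-bath exposures and no logistic volume
#'   cap (TRUE) versus PK-coupled xenograft mode (FALSE).
#' @return a \code{ReactionNetwork}.
#' @examples
#' net <- buildNetwork(cellLineConfig("SKBR3"))
#' net
#' @export
buildNetwork <- function(cellLine = cellLineConfig("SKBR3"),
                         signaling = signalingParams(),
                         drugs = c("lapatinib", "pyrotinib", "tdm1", "tdxd",
                                   "capecitabine"),
                         mechanisms = NULL, pk = NULL, inVitro = TRUE) {
  stopifnot(is(cellLine, "CellLineConfig"))
  known <- c("lapatinib", "pyrotinib", "tdm1", "tdxd", "capecitabine")
  bad <- setdiff(drugs, known)
  if (length(bad))
    stop("unknown drug(s): ", paste(bad, collapse = ", "), call. = FALSE)
  params <- .assembleParams(cellLine, signaling, drugs, mechanisms, pk,
                            inVitro)
  reactions <- c(.cellReactions(), .drugReactions(drugs),
                 .pkReactions(drugs))
  ## patch DAR/cellconv in processing stoichiometries from assembled params
  for (i in seq_along(reactions)) {
    st <- reactions[[i]]$stoich
    if (grepl("lysosomal_processing", reactions[[i]]$name)) {
      dar <- if (grepl("^tdm1", reactions[[i]]$name)) params[["DAR1"]]
             else params[["DAR2"]]
      st[2] <- dar
      reactions[[i]]$stoich <- st
    }
    if (reactions[[i]]$name %in% c("dm1_efflux",
                                   "dxd_membrane_permeation")) {
      st[2] <- params[["cellconv"]]
      reactions[[i]]$stoich <- st
    }
  }
  nm <- names(stateTemplate())
  species <- data.frame(name = nm, unit = unname(.speciesUnits()),
                        initial = unname(.initialState(cellLine, params)),
                        stringsAsFactors = FALSE)
  S <- matrix(0, nrow = length(nm), ncol = length(reactions),
              dimnames = list(nm, vapply(reactions, `[[`, "", "name")))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  new("ReactionNetwork", species = species, reactions = reactions,
      stoichiometry = S, params = params, cellLine = cellLine,
      drugs = drugs)
}

## initial condition: configured receptor counts, signaling pools inactive
.initialState <- function(cellLine, params) {
  y <- stateTemplate()
  rc <- cellLine@receptors
  y["E1"] <- rc[["EGFR"]]; y["E2"] <- rc[["HER2"]]
  y["E3"] <- rc[["HER3"]]; y["E4"] <- rc[["HER4"]]
  y["NCELL"] <- 1
  y
}

## map structured records onto the canonical parameter vector
.assembleParams <- function(cellLine, signaling, drugs, mechanisms, pk,
                            inVitro) {
  p <- paramTemplate()
  sig <- signaling
  p[names(sig)] <- unlist(sig)
  rc <- cellLine@receptors
  p["ksyn1"] <- p[["kdeg1"]] * rc[["EGFR"]]
  p["ksyn2"] <- p[["kdeg2"]] * rc[["HER2"]]
  p["ksyn3"] <- p[["kdeg3"]] * rc[["HER3"]]
  p["ksyn4"] <- p[["kdeg4"]] * rc[["HER4"]]
  g <- cellLine@growth
  p[names(g)] <- unlist(g)
  if (!is.null(mechanisms)) {
    for (m in mechanisms) {
      p <- switch(m$drug,
        lapatinib = {
          p["Kd_lap"] <- m$Kd; p["prot_lap"] <- m$prot
          p["degfold_lap"] <- m$degfold; p },
        pyrotinib = {
          p["kinact_pyr"] <- m$kinact; p["krec_pyr"] <- m$krec
          p["degfold_pyr"] <- m$degfold; p },
        tdm1 = {
          p["konA1"] <- m$kon; p["koffA1"] <- m$koff
          p["kint_ADC1"] <- m$kint_ADC; p["kdeg_ADC_2_1"] <- m$kdeg_ADC_2
          p["DAR1"] <- m$DAR; p["kout_PL"] <- m$kout_PL; p },
        tdxd = {
          p["konA2"] <- m$kon; p["koffA2"] <- m$koff
          p["kint_ADC2"] <- m$kint_ADC; p["kdeg_ADC_2_2"] <- m$kdeg_ADC_2
          p["DAR2"] <- m$DAR; p["kper_PL"] <- m$kper_PL; p },
        capecitabine = {
          p["w15"] <- m$w15; p["km10"] <- m$km10; p["n10"] <- m$n10; p })
    }
  }
  if (!is.null(pk)) {
    for (pkp in pk) {
      bw <- pkp$bw
      p <- switch(pkp$drug,
        lapatinib = {
          p["lap_ka"] <- pkp$ka; p["lap_CL"] <- pkp$CL * bw
          p["lap_Vc"] <- pkp$Vc * bw; p["lap_Q"] <- pkp$Q * bw
          p["lap_Vp"] <- pkp$Vp * bw; p["Kp_lap"] <- pkp$Kp; p },
        pyrotinib = {
          p["pyr_ka"] <- pkp$ka; p["pyr_CL"] <- pkp$CL * bw
          p["pyr_Vc"] <- pkp$Vc * bw; p["pyr_Q"] <- pkp$Q * bw
          p["pyr_Vp"] <- pkp$Vp * bw; p["Kp_pyr"] <- pkp$Kp; p },
        tdm1 = {
          p["tdm1_CL"] <- pkp$CL * bw; p["tdm1_Vc"] <- pkp$Vc * bw
          p["tdm1_Q"] <- pkp$Q * bw; p["tdm1_Vp"] <- pkp$Vp * bw
          p["tdm1_krel"] <- pkp$krel; p["tdm1_CLpl"] <- pkp$CLpl * bw
          p["tdm1_Vcpl"] <- pkp$Vcpl * bw; p["tdm1_Qpl"] <- pkp$Qpl * bw
          p["tdm1_Vppl"] <- pkp$Vppl * bw
          p["ktu1"] <- pkp$k_tu; p["kelim_tu1"] <- pkp$kelim_tu; p },
        tdxd = {
          p["tdxd_CL"] <- pkp$CL * bw; p["tdxd_Vc"] <- pkp$Vc * bw
          p["tdxd_Q"] <- pkp$Q * bw; p["tdxd_Vp"] <- pkp$Vp * bw
          p["tdxd_krel"] <- pkp$krel; p["tdxd_CLpl"] <- pkp$CLpl * bw
          p["tdxd_Vcpl"] <- pkp$Vcpl * bw; p["tdxd_Qpl"] <- pkp$Qpl * bw
          p["tdxd_Vppl"] <- pkp$Vppl * bw
          p["ktu2"] <- pkp$k_tu; p["kelim_tu2"] <- pkp$kelim_tu; p },
        capecitabine = {
          p["cap_ka"] <- pkp$ka; p["cap_k1"] <- pkp$k1
          p["cap_k2"] <- pkp$k2; p["cap_k3"] <- pkp$k3
          p["cap_CL"] <- pkp$CL * bw; p["cap_CLdfcr"] <- pkp$CLdfcr * bw
          p["cap_CLdfur"] <- pkp$CLdfur * bw; p["cap_CLfu"] <- pkp$CLfu * bw
          p["cap_V"] <- pkp$V * bw; p["cap_Vmet"] <- pkp$Vmet * bw
          p["Kp_FU"] <- pkp$Kp; p })
    }
  }
  p["f_invitro"] <- as.numeric(inVitro)
  p["f_pk"] <- as.numeric(!inVitro)
  if (any(p[grep("^(k|w|km|n|DAR|V|cells|u|d)", names(p))] < 0))
    stop("negative rate in assembled parameter vector", call. = FALSE)
  p
}

#' Evaluate the network right-hand side by naive per-reaction interpretation
#'
#' Sums stoichiometry-weighted per-reaction fluxes one reaction at a time.
#' This is the reference (slow) evaluation of the model derivatives; the
#' compiled right-hand side used by the simulators is verified against it.
#'
#' @param network a \code{ReactionNetwork}.
#' @param y named state vector (canonical order).
#' @param params optional parameter override (defaults to the network's).
#' @return named derivative vector.
#' @export
interpretRHS <- function(network, y, params = NULL) {
  p <- if (is.null(params)) network@params else params
  aux <- .modelAux(y, p)
  dy <- numeric(length(y))
  names(dy) <- names(y)
  for (rx in network@reactions) {
    v <- rx$rate(y, p, aux)
    st <- rx$stoich
    dy[names(st)] <- dy[names(st)] + st * v
  }
  dy
}

#' Receptor-monomer totals of a state
#'
#' Sums each ErbB receptor over its free, ligand-bound, dimerized,
#' phosphorylated and internalized forms (monomer equivalents). Used by the
#' conservation checks.
#'
#' @param y named state vector or a states matrix with named columns.
#' @return named vector (or matrix) with EGFR, HER2, HER3, HER4 totals.
#' @export
receptorTotals <- function(y) {
  g <- function(nm) if (is.matrix(y)) y[, nm, drop = TRUE] else y[[nm]]
  dim2 <- g("D12") + g("pD12") + 2 * (g("D22") + g("pD22")) +
    g("D23") + g("pD23") + g("D32") + g("pD32") + g("D42") + g("pD42")
  out <- cbind(
    EGFR = g("E1") + g("LE1") + g("D12") + g("pD12"),
    HER2 = g("E2") + dim2 + g("CPX1") + g("INT1") + g("CPX2") + g("INT2"),
    HER3 = g("E3") + g("NE3") + g("D23") + g("pD23") + g("D32") + g("pD32"),
    HER4 = g("E4") + g("NE4") + g("D42") + g("pD42"))
  if (!is.matrix(y)) out[1, ] else out
}
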