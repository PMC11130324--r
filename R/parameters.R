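## Canonical state and parameter orderings for the compiled model.
## The C right-hand side (src/model.c) indexes both by position, so the
## order here is load-bearing; the network-interpreter cross-check in the
## test suite guards against drift.

#' State template of the full model
#'
#' Named vector of all 58 model species in canonical order: free ErbB
#' receptors, ligand complexes, the five dimer types with their
#' phosphorylated forms, PI3K/AKT and Raf/ERK pools (fractional, total 1),
#' pyrotinib covalent occupancies, ADC processing chains for T-DM1 and
#' T-DXd, the tumor cell count, and the PK compartments of the five drugs.
#'
#' @return named numeric vector (all zeros except signaling pools).
#' @export
stateTemplate <- function() {
  s <- c(
    E1 = 0, E2 = 0, E3 = 0, E4 = 0,
    LE1 = 0, NE3 = 0, NE4 = 0,
    D12 = 0, pD12 = 0, D22 = 0, pD22 = 0, D23 = 0, pD23 = 0,
    D32 = 0, pD32 = 0, D42 = 0, pD42 = 0,
    PI3K = 1, pPI3K = 0, AKT = 1, pAKT = 0,
    RAF = 1, pRAF = 0, ERK = 1, pERK = 0,
    thP1 = 0, thP2 = 0, thP4 = 0,
    ADC1 = 0, CPX1 = 0, INT1 = 0, PIN1 = 0, PEX1 = 0,
    ADC2 = 0, CPX2 = 0, INT2 = 0, PIN2 = 0, PEX2 = 0,
    NCELL = 1,
    GLAP = 0, CLAPC = 0, CLAPP = 0,
    GPYR = 0, CPYRC = 0, CPYRP = 0,
    A1C = 0, A1P = 0, PL1C = 0, PL1P = 0,
    A2C = 0, A2P = 0, PL2C = 0, PL2P = 0,
    GCAP = 0, ACAP = 0, DFCR = 0, DFUR = 0, AFU = 0
  )
  s
}

#' Parameter template of the full model
#'
#' Named vector of all model parameters in the canonical order expected by
#' the compiled right-hand side, filled with the calibrated SKBR3 in vitro
#' baseline. Rates are per hour (proliferation/death rates \code{umax},
#' \code{dmax} are per day and converted internally); cellular abundances
#' are molecules/cell; medium and tumor drug/ligand concentrations are nM;
#' PK amounts are mg with absolute volumes in L (20 g mouse).
#'
#' @return named numeric vector of length 147.
#' @export
paramTemplate <- function() {
  c(
    ## receptor turnover + FOXO feedback on HER3 synthesis
    ksyn1 = 150000 * 0.07, ksyn2 = 1.5e6 * 0.07, ksyn3 = 40000 * 0.07,
    ksyn4 = 2000 * 0.07,
    kdeg1 = 0.07, kdeg2 = 0.07, kdeg3 = 0.07, kdeg4 = 0.07,
    kint_lig = 0.15, fb_fold = 2, km_fb = 0.1,
    ## ligand binding (1/(nM h), 1/h)
    kEGFon = 3.6, kEGFoff = 7.2, k8on = 3.6, k8off = 7.2,
    kNRG4on = 3.6, kNRG4off = 7.2,
    ## dimerization (1/(molecules/cell h), 1/h)
    kon12 = 3e-5, koff12 = 10, kon22 = 1e-6, koff22 = 10,
    kon23 = 1e-6, koff23 = 10, kon32 = 1e-5, koff32 = 10,
    kon42 = 1e-5, koff42 = 10,
    ## transphosphorylation
    kphos = 60, kdeph = 60,
    ## PI3K/AKT cascade
    kon_PI3K = 20, koff_PI3K = 10, km_PI3K = 1.4e5, n_PI3K = 2, w_her3 = 30,
    kon_AKT = 20, koff_AKT = 10, km_AKTact = 0.5, n_AKTact = 2,
    ## Raf/ERK cascade
    kon_Raf = 10, koff_Raf = 20, w7 = 1, km7 = 1.4e5, n7 = 2,
    kon_ERK = 20, koff_ERK = 20, w8 = 1, km8 = 0.2, n8 = 2,
    ## growth-signal integration
    w11 = 1.3, km11 = 0.34, n11 = 2, wAKT = 0.6, km_AKTg = 0.5, n_AKTg = 2,
    w_basal = 0.15, w_btk = 0, km_btk = 5,
    ## tumor growth/death (umax, dmax per day)
    umax = 0.6, dmax = 0.15, km13 = 0.5, n13 = 2,
    w14_dm1 = 4, km14_dm1 = 4e3, n14_dm1 = 1,
    w14_dxd = 4, km14_dxd = 1.2e3, n14_dxd = 1,
    w15 = 4, km10 = 5000, n10 = 1,
    Vmax = 2000, cells_per_mm3 = 1e6,
    ## TKI mechanism
    Kd_lap = 3, prot_lap = 100, kinact_pyr = 0.06, krec_pyr = 0.05,
    degfold_lap = 3, degfold_pyr = 4,
    ## ADC cell-level processing (T-DM1 then T-DXd)
    konA1 = 0.01, koffA1 = 0.2, kint_ADC1 = 0.1, kdeg_ADC_2_1 = 0.02,
    DAR1 = 3.5, kout_PL = 1, kelim_pex1 = 0.05,
    konA2 = 0.01, koffA2 = 0.2, kint_ADC2 = 0.1, kdeg_ADC_2_2 = 0.02,
    DAR2 = 8, kper_PL = 2, kelim_pex2 = 0.05,
    volfac = 1204, cellconv = 1.7e-7,
    ktu1 = 0.17, kelim_tu1 = 0.05, ktu2 = 0.17, kelim_tu2 = 0.05,
    ## constant bath stimuli (nM)
    bath_EGF = 0, bath_NRG1 = 0, bath_lap = 0, bath_pyr = 0, bath_FU = 0,
    ## PK (absolute for a 20 g mouse)
    lap_ka = 0.5, lap_CL = 0.034, lap_Vc = 0.4, lap_Q = 0.02, lap_Vp = 0.4,
    Kp_lap = 0.0008,
    pyr_ka = 1, pyr_CL = 0.06, pyr_Vc = 0.1, pyr_Q = 0.02, pyr_Vp = 0.2,
    Kp_pyr = 1,
    tdm1_CL = 8e-6, tdm1_Vc = 1e-3, tdm1_Q = 4e-5, tdm1_Vp = 2e-3,
    tdm1_krel = 0.005, tdm1_CLpl = 0.01, tdm1_Vcpl = 0.02,
    tdm1_Qpl = 2e-3, tdm1_Vppl = 0.02,
    tdxd_CL = 1e-5, tdxd_Vc = 1e-3, tdxd_Q = 4e-5, tdxd_Vp = 2e-3,
    tdxd_krel = 0.006, tdxd_CLpl = 0.01, tdxd_Vcpl = 0.02,
    tdxd_Qpl = 2e-3, tdxd_Vppl = 0.02,
    cap_ka = 2, cap_k1 = 3, cap_k2 = 3, cap_k3 = 1.5,
    cap_CL = 0.06, cap_CLdfcr = 0.06, cap_CLdfur = 0.06, cap_CLfu = 0.06,
    cap_V = 0.04, cap_Vmet = 0.04, Kp_FU = 1,
    ## mode switches
    f_invitro = 1, f_turnover = 1, f_pk = 0,
    ## HER2 homodimer signaling weight (HER2-HER3/HER4 units dominate)
    w22 = 0.2,
    ## recycling/expulsion of internalized ADC without payload release
    krec_ADC1 = 0.04, krec_ADC2 = 0.04,
    ## signaling weight of the ligand-independent HER2-HER3 dimer
    ## (liganded NRG1 dimers signal more strongly; see w_her3)
    w_her3_basal = 6
  )
}

## molecular weights used for unit conversions
.MW <- c(EGF = 6.2, NRG1 = 7.5,           # kDa (ligands; ng/mL -> nM)
         lapatinib = 581.06, pyrotinib = 583.06, FU = 130.08,  # g/mol
         ADC = 148000)                    # g/mol (IgG conjugate)

#' Convert a ligand dose from ng/mL to nM
#'
#' Uses the configured ligand molecular weights (EGF 6.2 kDa, NRG1 active
#' domain 7.5 kDa).
#'
#' @param ligand "EGF" or "NRG1".
#' @param ng_per_mL dose in ng/mL (>= 0).
#' @return concentration in nM.
#' @export
ligandToNM <- function(ligand, ng_per_mL) {
  ligand <- match.arg(ligand, c("EGF", "NRG1"))
  .assertNonNeg(ng_per_mL, "ng_per_mL")
  ng_per_mL / .MW[[ligand]]
}

#' Signaling parameter record
#'
#' Returns the calibrated baseline signaling parameters (ligand binding,
#' dimerization, transphosphorylation, cascade activation, FOXO feedback,
#' receptor turnover) as a named list. Override any subset via \code{...}.
#'
#' @param ... named overrides, e.g. \code{k8on = 1.8}.
#' @return named list of signaling rates.
#' @export
signalingParams <- function(...) {
  tmpl <- paramTemplate()
  keep <- c("ksyn1", "ksyn2", "ksyn3", "ksyn4", "kdeg1", "kdeg2", "kdeg3",
            "kdeg4", "kint_lig", "fb_fold", "km_fb", "kEGFon", "kEGFoff",
            "k8on", "k8off", "kNRG4on", "kNRG4off", "kon12", "koff12",
            "kon22", "koff22", "kon23", "koff23", "kon32", "koff32",
            "kon42", "koff42", "kphos", "kdeph", "kon_PI3K", "koff_PI3K",
            "km_PI3K", "n_PI3K", "w_her3", "kon_AKT", "koff_AKT",
            "km_AKTact", "n_AKTact", "kon_Raf", "koff_Raf", "w7", "km7",
            "n7", "kon_ERK", "koff_ERK", "w8", "km8", "n8", "w11", "km11",
            "n11", "wAKT", "km_AKTg", "n_AKTg", "w_basal", "w_btk",
            "km_btk", "w22", "w_her3_basal")
  out <- as.list(tmpl[keep])
  out <- .applyOverrides(out, list(...))
  .validateRates(out)
  out
}

#' Growth/death parameter record
#'
#' Tumor proliferation/death law parameters. \code{umax} and \code{dmax} are
#' per day; Hill constants govern the pro-growth signal (km13, n13), the
#' ADC-payload death stimuli (w14/km14/n14 per payload) and the 5-FU death
#' stimulus (w15, km10, n10). In vivo values are the translated (re-estimated)
#' set; in vitro values drive viability assays.
#'
#' @param inVivo logical; return the in vivo (xenograft) set.
#' @param ... named overrides.
#' @return named list.
#' @export
growthDeathParams <- function(inVivo = FALSE, ...) {
  tmpl <- paramTemplate()
  keep <- c("umax", "dmax", "km13", "n13", "w14_dm1", "km14_dm1", "n14_dm1",
            "w14_dxd", "km14_dxd", "n14_dxd", "w15", "km10", "n10",
            "Vmax", "cells_per_mm3")
  out <- as.list(tmpl[keep])
  if (inVivo) {
    out$umax <- 0.25
    out$dmax <- 0.05
  }
  out <- .applyOverrides(out, list(...))
  if (out$umax <= out$dmax)
    stop("growth/death parameters must satisfy umax > dmax", call. = FALSE)
  .validateRates(out[setdiff(names(out), c("n13", "n14_dm1", "n14_dxd",
                                           "n10"))])
  out
}

#' Drug mechanism parameter record
#'
#' Mechanistic cell-level parameters for one drug: reversible TKI
#' (lapatinib: EGFR+HER2, Kd, NRG1-protection factor), irreversible TKI
#' (pyrotinib: EGFR+HER2+HER4, covalent inactivation), ADC (binding,
#' internalization kint_ADC, lysosomal processing kdeg_ADC_2, DAR, payload
#' efflux kout_PL for DM1 / bidirectional permeation kper_PL for DXd), or
#' chemo payload (5-FU death stimulus, parameterized in growthDeathParams).
#'
#' @param drug one of "lapatinib", "pyrotinib", "tdm1", "tdxd",
#'   "capecitabine".
#' @param ... named overrides of the mechanism fields.
#' @return named list with elements \code{drug}, \code{kind},
#'   \code{targets}, and mechanism rates.
#' @export
drugMechanism <- function(drug = c("lapatinib", "pyrotinib", "tdm1", "tdxd",
                                   "capecitabine"), ...) {
  drug <- match.arg(drug)
  tmpl <- paramTemplate()
  mech <- switch(drug,
    lapatinib = list(kind = "TKI_reversible",
                     targets = c("EGFR", "HER2"),
                     Kd = tmpl[["Kd_lap"]], prot = tmpl[["prot_lap"]],
                     degfold = tmpl[["degfold_lap"]]),
    pyrotinib = list(kind = "TKI_irreversible",
                     targets = c("EGFR", "HER2", "HER4"),
                     kinact = tmpl[["kinact_pyr"]],
                     krec = tmpl[["krec_pyr"]],
                     degfold = tmpl[["degfold_pyr"]]),
    tdm1 = list(kind = "ADC", targets = "HER2",
                kon = tmpl[["konA1"]], koff = tmpl[["koffA1"]],
                kint_ADC = tmpl[["kint_ADC1"]],
                kdeg_ADC_2 = tmpl[["kdeg_ADC_2_1"]],
                DAR = tmpl[["DAR1"]], kout_PL = tmpl[["kout_PL"]],
                reentry = FALSE),
    tdxd = list(kind = "ADC", targets = "HER2",
                kon = tmpl[["konA2"]], koff = tmpl[["koffA2"]],
                kint_ADC = tmpl[["kint_ADC2"]],
                kdeg_ADC_2 = tmpl[["kdeg_ADC_2_2"]],
                DAR = tmpl[["DAR2"]], kper_PL = tmpl[["kper_PL"]],
                reentry = TRUE),
    capecitabine = list(kind = "chemo_payload", targets = character(0),
                        w15 = tmpl[["w15"]], km10 = tmpl[["km10"]],
                        n10 = tmpl[["n10"]]))
  mech <- .applyOverrides(mech, list(...))
  numfields <- vapply(mech, is.numeric, logical(1))
  .validateRates(mech[numfields & !(names(mech) %in% "n10")])
  c(list(drug = drug), mech)
}

.applyOverrides <- function(base, overrides) {
  if (length(overrides) == 0L) return(base)
  bad <- setdiff(names(overrides), names(base))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  base[names(overrides)] <- overrides
  base
}

.validateRates <- function(lst) {
  num <- vapply(lst, function(x) is.numeric(x) && length(x) == 1L,
                logical(1))
  vals <- unlist(lst[num])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate parameters must be finite and non-negative",
         call. = FALSE)
  hills <- grep("^n", names(vals), value = TRUE)
  if (length(hills) && any(vals[hills] < 1))
    stop("Hill exponents must be >= 1", call. = FALSE)
  invisible(lst)
}

#' PK parameter record for one drug
#'
#' Two-compartment mouse PK (oral first-order absorption for TKIs and
#' capecitabine, IV bolus for ADCs), ADC deconjugation/catabolite
#' disposition, the capecitabine metabolite cascade, and the tumor-exposure
#' coupling (partition coefficient \code{Kp} for TKIs/5-FU; first-order
#' tumor entry \code{k_tu} for ADCs). Clearances/volumes are per kg; they are
#' scaled by the animal body weight when the model is assembled. Defaults
#' are provisional (calibrated to reproduce the expected curve shapes).
#'
#' @param drug drug name.
#' @param bw body weight in kg (default 0.02, a 20 g mouse).
#' @param ... named overrides (per-kg scale).
#' @return named list with fields \code{drug}, \code{route}, per-kg rates,
#'   and \code{bw}.
#' @export
pkParams <- function(drug = c("lapatinib", "pyrotinib", "tdm1", "tdxd",
                              "capecitabine"), bw = 0.02, ...) {
  drug <- match.arg(drug)
  base <- switch(drug,
    lapatinib = list(route = "oral", ka = 0.5, CL = 1.7, Vc = 20, Q = 1,
                     Vp = 20, Kp = 0.0008),
    pyrotinib = list(route = "oral", ka = 1, CL = 3, Vc = 5, Q = 1, Vp = 10,
                     Kp = 1),
    tdm1 = list(route = "iv", CL = 4e-4, Vc = 0.05, Q = 2e-3, Vp = 0.1,
                krel = 0.005, CLpl = 0.5, Vcpl = 1, Qpl = 0.1, Vppl = 1,
                k_tu = 0.17, kelim_tu = 0.05),
    tdxd = list(route = "iv", CL = 5e-4, Vc = 0.05, Q = 2e-3, Vp = 0.1,
                krel = 0.006, CLpl = 0.5, Vcpl = 1, Qpl = 0.1, Vppl = 1,
                k_tu = 0.17, kelim_tu = 0.05),
    capecitabine = list(route = "oral", ka = 2, k1 = 3, k2 = 3, k3 = 1.5,
                        CL = 3, CLdfcr = 3, CLdfur = 3, CLfu = 3, V = 2,
                        Vmet = 2, Kp = 1))
  base <- .applyOverrides(base, list(...))
  vols <- intersect(names(base), c("Vc", "Vp", "Vcpl", "Vppl", "V", "Vmet"))
  if (any(unlist(base[vols]) <= 0))
    stop("PK volumes must be > 0", call. = FALSE)
  .validateRates(base[setdiff(names(base), "route")])
  c(list(drug = drug, bw = bw), base)
}
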