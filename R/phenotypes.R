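## Heterogeneous response phenotypes: named parameter-override presets that
## reproduce the qualitative resistance patterns, plus the
## phenotype x regimen TGI grid.

.phenotypePresets <- function() list(
  sensitive = list(mult = c(), abs = c(), stim = c()),
  ## increased efflux of DM1 catabolites
  tdm1_resistant = list(mult = c(kout_PL = 50), abs = c(), stim = c()),
  ## faster proliferation + aberrant Raf/MAPK transduction
  lapatinib_resistant = list(mult = c(umax = 1.5, kon_Raf = 8),
                             abs = c(), stim = c()),
  ## further increased proliferation on top of the MAPK lesion
  pan_resistant = list(mult = c(umax = 2, kon_Raf = 8), abs = c(),
                       stim = c()),
  ## constant NRG1 bath (50 ng/mL)
  nrg1_over = list(mult = c(), abs = c(),
                   stim = c(NRG1 = 50 / 7.5)),
  ## blocking NRG1-HER3 binding (HER3 antibody surrogate)
  her3_mab = list(mult = c(), abs = c(k8on = 0), stim = c()),
  ## reduced PI3K activation (PI3K inhibitor surrogate)
  pi3k_inhibited = list(mult = c(kon_PI3K = 0.2), abs = c(), stim = c()),
  ## growth highly dependent on PI3K/AKT (constitutive-like activation)
  pik3ca_dependent = list(mult = c(wAKT = 3, w11 = 0.3, km_PI3K = 0.05),
                          abs = c(), stim = c()))

#' Create a named response phenotype
#'
#' Returns one of the preset phenotypes as parameter multipliers /
#' absolute overrides plus stimulus overrides. Defaults (calibrated so the
#' qualitative response patterns hold): tdm1_resistant = kout_PL x50;
#' lapatinib_resistant = umax x1.5 and kon_Raf x8; pan_resistant = umax x2
#' and kon_Raf x8; nrg1_over = constant NRG1 bath 50 ng/mL; her3_mab =
#' k8on -> 0; pi3k_inhibited = PI3K activation x0.2; pik3ca_dependent =
#' AKT-weighted growth with constitutive-like PI3K activation.
#' Phenotypes compose: pass several to \code{\link{applyPhenotype}}.
#'
#' @param name preset name.
#' @param multipliers optional named multipliers overriding the preset's.
#' @param stimuli optional named stimulus overrides (nM).
#' @return a \code{\linkS4class{Phenotype}}.
#' @export
makePhenotype <- function(name, multipliers = NULL, stimuli = NULL) {
  presets <- .phenotypePresets()
  if (!name %in% names(presets))
    stop("unknown phenotype '", name, "'; presets: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  pre <- presets[[name]]
  mult <- pre$mult
  if (!is.null(multipliers)) mult[names(multipliers)] <- multipliers
  stim <- pre$stim
  if (!is.null(stimuli)) stim[names(stimuli)] <- stimuli
  badm <- setdiff(names(mult), names(paramTemplate()))
  bada <- setdiff(names(pre$abs), names(paramTemplate()))
  if (length(c(badm, bada)))
    stop("phenotype references unknown parameter(s): ",
         paste(c(badm, bada), collapse = ", "), call. = FALSE)
  new("Phenotype", name = name,
      multipliers = if (length(mult)) mult else numeric(0),
      absolutes = if (length(pre$abs)) pre$abs else numeric(0),
      stimuli = if (length(stim)) stim else numeric(0))
}

#' Apply phenotypes to a network
#'
#' Multiplies/overrides the network's parameters and merges stimulus
#' overrides. Several phenotypes compose left to right.
#'
#' @param network a \code{ReactionNetwork}.
#' @param ... one or more \code{Phenotype} objects.
#' @param stim0 base stimulus record.
#' @return list(network = modified network, stim = merged stimulus).
#' @export
applyPhenotype <- function(network, ..., stim0 = stimulus()) {
  phens <- list(...)
  p <- network@params
  stim <- stim0
  for (ph in phens) {
    stopifnot(is(ph, "Phenotype"))
    for (nm in names(ph@multipliers))
      p[nm] <- p[[nm]] * ph@multipliers[[nm]]
    for (nm in names(ph@absolutes))
      p[nm] <- ph@absolutes[[nm]]
    for (nm in names(ph@stimuli))
      stim[[nm]] <- ph@stimuli[[nm]]
  }
  net <- network
  net@params <- p
  list(network = net, stim = stim)
}

#' The 13-arm regimen panel
#'
#' The standard panel used for phenotype profiling (doses per the
#' xenograft convention: lapatinib 100 mg/kg qd; pyrotinib 30 mg/kg qd;
#' capecitabine 400 mg/kg d1-d14; T-DM1 30 mg/kg q3w; T-DXd 10 mg/kg q3w),
#' ordered: the five single agents, TKI+capecitabine doubles, pyrotinib+ADC
#' doubles, lapatinib+capecitabine+ADC triples, pyrotinib+capecitabine+ADC
#' triples.
#'
#' @return named list of 13 \code{\linkS4class{Regimen}} objects.
#' @export
regimenPresets <- function() {
  lap <- function() regimenArm("lapatinib", 100, "qd")
  pyr <- function() regimenArm("pyrotinib", 30, "qd")
  cap <- function() regimenArm("capecitabine", 400, "d1-d14")
  tdm1 <- function() regimenArm("tdm1", 30, "q3w")
  tdxd <- function() regimenArm("tdxd", 10, "q3w")
  list(
    lapatinib = regimen(lap()),
    pyrotinib = regimen(pyr()),
    capecitabine = regimen(cap()),
    tdm1 = regimen(tdm1()),
    tdxd = regimen(tdxd()),
    `lapatinib+capecitabine` = regimen(lap(), cap()),
    `pyrotinib+capecitabine` = regimen(pyr(), cap()),
    `pyrotinib+tdm1` = regimen(pyr(), tdm1()),
    `pyrotinib+tdxd` = regimen(pyr(), tdxd()),
    `lapatinib+capecitabine+tdm1` = regimen(lap(), cap(), tdm1()),
    `lapatinib+capecitabine+tdxd` = regimen(lap(), cap(), tdxd()),
    `pyrotinib+capecitabine+tdm1` = regimen(pyr(), cap(), tdm1()),
    `pyrotinib+capecitabine+tdxd` = regimen(pyr(), cap(), tdxd()))
}

#' Phenotype x regimen TGI grid
#'
#' Simulates each phenotype under each regimen (plus a control arm per
#' phenotype) and reports TGI at the evaluation day. Arm ordering follows
#' the supplied regimen list and is stable.
#'
#' @param phenotypes list of \code{Phenotype} objects (or names).
#' @param regimens named list of \code{Regimen} objects (default the
#'   13-arm panel).
#' @param day TGI evaluation day (default 20: one 21-day cycle).
#' @param network base in vivo network (defaults to the calibrated SKBR3
#'   xenograft configuration).
#' @param startVolume mm3.
#' @return phenotypes x regimens matrix of TGI percentages.
#' @export
phenotypeRegimenGrid <- function(phenotypes, regimens = regimenPresets(),
                                 day = 20, network = NULL,
                                 startVolume = 80) {
  if (is.null(network))
    network <- buildNetwork(
      cellLineConfig("SKBR3", growth = growthDeathParams(inVivo = TRUE)),
      inVitro = FALSE)
  phenotypes <- lapply(phenotypes, function(ph)
    if (is.character(ph)) makePhenotype(ph) else ph)
  followUp <- day + 1
  out <- matrix(NA_real_, length(phenotypes), length(regimens),
                dimnames = list(vapply(phenotypes, function(p) p@name, ""),
                                names(regimens)))
  for (i in seq_along(phenotypes)) {
    app <- applyPhenotype(network, phenotypes[[i]])
    ctrl <- runXenograft(app$network, regimen(), followUp, startVolume,
                         stim0 = app$stim)
    for (j in seq_along(regimens)) {
      trt <- runXenograft(app$network, regimens[[j]], followUp,
                          startVolume, stim0 = app$stim)
      out[i, j] <- computeTGI(trt, ctrl, day)
    }
  }
  out
}

#' Simulate acquired resistance by exposure-driven potency decay
#'
#' Optional hook (off in all standard protocols): tumor growth is
#' simulated cycle by cycle and after each 21-day cycle the payload/TKI
#' potency half-saturation constants are inflated by
#' \code{exp(decay x cycle number)}, emulating progressive loss of drug
#' potency with cumulative exposure.
#'
#' @param network in vivo network.
#' @param reg a \code{Regimen}.
#' @param cycles number of 21-day cycles.
#' @param decay per-cycle log-fold potency loss (0 = no acquired
#'   resistance).
#' @param startVolume mm3.
#' @return data.frame(day, volume) across all cycles.
#' @export
simulateAcquiredResistance <- function(network, reg, cycles = 3,
                                       decay = 0, startVolume = 80) {
  vol <- startVolume
  out <- NULL
  net <- network
  for (cy in seq_len(cycles)) {
    res <- runXenograft(net, reg, 21, vol)
    res$day <- res$day + (cy - 1) * 21
    out <- rbind(out, if (cy == 1) res else res[-1, ])
    vol <- res$volume[nrow(res)]
    for (nm in c("km14_dm1", "km14_dxd", "km10", "Kd_lap"))
      net@params[nm] <- net@params[[nm]] * exp(decay)
    net@params["kinact_pyr"] <- net@params[["kinact_pyr"]] * exp(-decay)
  }
  out
}
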