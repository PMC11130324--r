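## Simulation front-end over the compiled model (deSolve, stiff-capable
## lsoda integrator).

#' Stimulus record
#'
#' A constant-bath stimulus/exposure record for cell-level simulations:
#' ligand concentrations (nM), TKI concentrations (nM), ADC concentrations
#' (nM) and 5-FU (nM). In xenograft mode the drug exposures are instead
#' driven by the PK module and only ligand baths apply.
#'
#' @param EGF,NRG1 ligand baths in nM (see \code{\link{applyLigand}} for
#'   ng/mL dosing).
#' @param lapatinib,pyrotinib TKI baths in nM.
#' @param tdm1,tdxd ADC baths in nM.
#' @param fu 5-FU bath in nM (capecitabine's active metabolite; used
#'   directly in vitro).
#' @return a named list of class "qsp_stimulus".
#' @export
stimulus <- function(EGF = 0, NRG1 = 0, lapatinib = 0, pyrotinib = 0,
                     tdm1 = 0, tdxd = 0, fu = 0) {
  out <- list(EGF = EGF, NRG1 = NRG1, lapatinib = lapatinib,
              pyrotinib = pyrotinib, tdm1 = tdm1, tdxd = tdxd, fu = fu)
  for (nm in names(out)) .assertNonNeg(out[[nm]], nm)
  class(out) <- "qsp_stimulus"
  out
}

#' Add a ligand to a stimulus record (ng/mL)
#'
#' Converts ng/mL to nM via the configured molecular weights (EGF 6.2 kDa,
#' NRG1 7.5 kDa) and sets a constant bath concentration.
#'
#' @param stim a \code{\link{stimulus}} record.
#' @param ligand "EGF" or "NRG1".
#' @param ng_per_mL dose (>= 0).
#' @export
applyLigand <- function(stim, ligand, ng_per_mL) {
  ligand <- match.arg(ligand, c("EGF", "NRG1"))
  stim[[ligand]] <- ligandToNM(ligand, ng_per_mL)
  stim
}

#' Add a TKI to a stimulus record (nM)
#'
#' @param stim a \code{\link{stimulus}} record.
#' @param drug "lapatinib" or "pyrotinib".
#' @param nM bath concentration (>= 0).
#' @export
applyTki <- function(stim, drug, nM) {
  drug <- match.arg(drug, c("lapatinib", "pyrotinib"))
  .assertNonNeg(nM, "nM")
  stim[[drug]] <- nM
  stim
}

#' Add an ADC to a stimulus record (nM)
#'
#' @param stim a \code{\link{stimulus}} record.
#' @param drug "tdm1" or "tdxd".
#' @param nM bath concentration (>= 0).
#' @export
applyAdc <- function(stim, drug, nM) {
  drug <- match.arg(drug, c("tdm1", "tdxd"))
  .assertNonNeg(nM, "nM")
  stim[[drug]] <- nM
  stim
}

## fold a stimulus record into the parameter vector / initial state
.applyStimulus <- function(params, y0, stim) {
  params["bath_EGF"] <- stim$EGF
  params["bath_NRG1"] <- stim$NRG1
  params["bath_lap"] <- stim$lapatinib
  params["bath_pyr"] <- stim$pyrotinib
  params["bath_FU"] <- stim$fu
  y0["ADC1"] <- stim$tdm1
  y0["ADC2"] <- stim$tdxd
  list(params = params, y0 = y0)
}

## solver wrapper: compiled RHS, negativity clamped at solver tolerance
.solve <- function(y0, times, params, events = NULL, atol = 1e-8,
                   rtol = 1e-8) {
  if (is.data.frame(events)) events <- list(data = events)
  out <- try(deSolve::ode(
    y = y0, times = times, func = "derivs", parms = unname(params),
    dllname = "qspHER2", initfunc = "initmod", method = "lsoda",
    atol = atol, rtol = rtol, maxsteps = 50000,
    events = events), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("integrator failure: ", attr(out, "condition")$message,
         call. = FALSE)
  m <- as.matrix(out)
  if (nrow(m) < length(times)) {
    lastGood <- m[nrow(m), 1]
    stop(sprintf("integrator failure; last good time %.4g h", lastGood),
         call. = FALSE)
  }
  states <- m[, -1, drop = FALSE]
  colnames(states) <- names(y0)
  ## clamp numerically tiny negatives (solver tolerance)
  states[states < 0 & states > -1e3 * atol] <- 0
  states
}

#' Initialize the model at its drug- and ligand-free steady state
#'
#' Integrates the network without external stimuli until the maximum
#' relative derivative over all signaling species falls below \code{tol},
#' reproducing the spontaneous (ligand-independent) HER2 homo-/heterodimer
#' steady state used as the initial condition for every experiment. The
#' tumor cell count is excluded from the criterion (it grows) and is reset
#' to its starting value.
#'
#' @param network a \code{\link{buildNetwork}} result.
#' @param tol steady-state tolerance on max relative derivative (1/h).
#' @param maxT maximum simulated horizon (h) before a convergence error.
#' @return named steady-state vector.
#' @export
initializeSteadyState <- function(network, tol = 1e-8, maxT = 10000) {
  p <- network@params
  p["bath_EGF"] <- 0; p["bath_NRG1"] <- 0; p["bath_lap"] <- 0
  p["bath_pyr"] <- 0; p["bath_FU"] <- 0
  y <- stateTemplate()
  y[] <- network@species$initial
  n0 <- y[["NCELL"]]
  skip <- c("NCELL")
  tEnd <- 0
  chunk <- 500
  repeat {
    states <- .solve(y, c(0, chunk), p)
    y <- states[nrow(states), ]
    y["NCELL"] <- n0
    tEnd <- tEnd + chunk
    dy <- .evalRHS(y, p)
    rel <- abs(dy) / pmax(abs(y), 1e-6)
    rel[skip] <- 0
    if (max(rel) < tol) break
    if (tEnd >= maxT)
      stop(sprintf(paste0("no steady state within %g h (max relative ",
                          "derivative %.3g)"), maxT, max(rel)),
           call. = FALSE)
  }
  y
}

## direct evaluation of the compiled derivatives at one state
.evalRHS <- function(y, params) {
  v <- deSolve::DLLfunc(func = "derivs", dllname = "qspHER2",
                        initfunc = "initmod", times = 0, y = unname(y),
                        parms = unname(params))$dy
  names(v) <- names(y)
  v
}

#' Simulate a time course
#'
#' Integrates the model from \code{state0} under a constant-bath stimulus
#' record for \code{duration} hours (stiff-capable integrator). Use
#' \code{\link{runXenograft}} for PK-driven in vivo protocols.
#'
#' @param network a \code{ReactionNetwork}.
#' @param state0 named initial state (typically from
#'   \code{\link{initializeSteadyState}}).
#' @param stimuli a \code{\link{stimulus}} record.
#' @param duration hours.
#' @param dt output resolution in hours.
#' @return a \code{\linkS4class{Trajectory}}.
#' @examples
#' \donttest{
#' net <- buildNetwork(cellLineConfig("SKBR3"))
#' ss <- initializeSteadyState(net)
#' tr <- simulateTimecourse(net, ss, stimulus(lapatinib = 100), 24)
#' readout(tr, "pERK")[c(1, length(trajTimes(tr)))]
#' }
#' @export
simulateTimecourse <- function(network, state0, stimuli = stimulus(),
                               duration = 24, dt = 0.25) {
  stopifnot(all(state0 >= 0))
  app <- .applyStimulus(network@params, state0, stimuli)
  times <- seq(0, duration, by = dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  states <- .solve(app$y0, times, app$params)
  new("Trajectory", times = times, states = states,
      inputs = list(stimulus = stimuli, params = app$params))
}

#' Extract a named readout from a trajectory
#'
#' Phospho-readouts are monomer-equivalent sums over the phosphorylated
#' dimers containing the receptor; totals sum free, ligand-bound, dimeric
#' and internalized forms; "volume" converts cells to mm3.
#'
#' @param traj a \code{Trajectory}.
#' @param name one of pEGFR, pHER2, pHER3, pHER4, pAKT, pERK, pRAF, pPI3K,
#'   EGFR_total, HER2_total, HER3_total, HER4_total, ncell, volume,
#'   payload_dm1, payload_dxd, or any species name.
#' @return numeric vector along \code{trajTimes(traj)}.
#' @export
readout <- function(traj, name) {
  s <- traj@states
  tot <- function(r) receptorTotals(s)[, r]
  switch(name,
    pEGFR = s[, "pD12"],
    pHER2 = s[, "pD12"] + 2 * s[, "pD22"] + s[, "pD23"] + s[, "pD32"] +
      s[, "pD42"],
    pHER3 = s[, "pD23"] + s[, "pD32"],
    pHER4 = s[, "pD42"],
    pAKT = s[, "pAKT"], pERK = s[, "pERK"], pRAF = s[, "pRAF"],
    pPI3K = s[, "pPI3K"],
    EGFR_total = tot("EGFR"), HER2_total = tot("HER2"),
    HER3_total = tot("HER3"), HER4_total = tot("HER4"),
    ncell = s[, "NCELL"],
    volume = s[, "NCELL"] / traj@inputs$params[["cells_per_mm3"]],
    payload_dm1 = s[, "PIN1"], payload_dxd = s[, "PIN2"],
    {
      if (!name %in% colnames(s)) stop("unknown readout '", name, "'",
                                       call. = FALSE)
      s[, name]
    })
}

#' Tumor growth/death rate law
#'
#' The scalar growth law: \code{dN/dt = N [umax Hill(S; km13, n13)
#' (1 - V/Vmax) - dmax (1 + w14 Hill(payload; km14, n14) +
#' w15 Hill(fu; km10, n10))]} with rates per day. In vitro the logistic
#' factor is 1. Exposed for direct use and for oracle tests of the full
#' model's growth component.
#'
#' @param N cell count (>= 0).
#' @param V tumor volume in mm3.
#' @param S_growth unitless pro-growth signal in [0, 1].
#' @param payload intracellular payload (molecules/cell).
#' @param fu 5-FU exposure (nM).
#' @param p growth/death parameter list (\code{\link{growthDeathParams}});
#'   payload Hill uses the DM1 fields.
#' @param inVitro logical.
#' @return dN/dt in cells/day.
#' @export
growthDeathRate <- function(N, V, S_growth, payload, fu, p,
                            inVitro = FALSE) {
  stopifnot(N >= 0)
  gfac <- if (inVitro) 1 else 1 - V / p$Vmax
  mu <- p$umax * hillFn(S_growth, p$km13, p$n13) * gfac
  death <- p$dmax * (1 + p$w14_dm1 * hillFn(payload, p$km14_dm1, p$n14_dm1)
                     + p$w15 * hillFn(fu, p$km10, p$n10))
  N * (mu - death)
}

#' Write a trajectory as tidy delimited text
#'
#' Long-format export: time, species, value, unit.
#'
#' @param traj a \code{Trajectory}.
#' @param file output path.
#' @param species optional subset of species names.
#' @export
writeTrajectory <- function(traj, file, species = NULL) {
  units <- .speciesUnits()
  nm <- colnames(traj@states)
  if (!is.null(species)) nm <- intersect(nm, species)
  long <- do.call(rbind, lapply(nm, function(sp)
    data.frame(time = traj@times, species = sp,
               value = traj@states[, sp], unit = units[[sp]],
               stringsAsFactors = FALSE)))
  utils::write.table(long, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
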