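## Mouse compartmental PK for the five drugs, with tumor-exposure coupling.

.doseTarget <- c(lapatinib = "GLAP", pyrotinib = "GPYR", tdm1 = "A1C",
                 tdxd = "A2C", capecitabine = "GCAP")
.defaultRoute <- c(lapatinib = "oral", pyrotinib = "oral", tdm1 = "iv",
                   tdxd = "iv", capecitabine = "oral")

#' Build a dose-event table
#'
#' Converts mg/kg doses at given times into absolute-amount (mg) bolus
#' events into the appropriate compartment: the gut depot for oral drugs,
#' the central compartment for IV ADCs. Body weight defaults to a 20 g
#' mouse.
#'
#' @param drug drug name.
#' @param dose mg/kg (scalar or one per time).
#' @param times dosing times in hours.
#' @param route "oral" or "iv" (defaults to the drug's clinical route).
#' @param bw body weight (kg).
#' @return data.frame with columns drug, time, amount (mg), route, var
#'   (target state).
#' @export
doseEvents <- function(drug, dose, times, route = NULL, bw = 0.02) {
  drug <- match.arg(drug, names(.doseTarget))
  .assertNonNeg(dose, "dose")
  if (is.null(route)) route <- .defaultRoute[[drug]]
  route <- match.arg(route, c("oral", "iv"))
  if (length(times) == 0L)
    return(data.frame(drug = character(), time = numeric(),
                      amount = numeric(), route = character(),
                      var = character(), stringsAsFactors = FALSE))
  dose <- rep_len(dose, length(times))
  data.frame(drug = drug, time = times, amount = dose * bw, route = route,
             var = if (route == "oral" && drug %in%
                         c("lapatinib", "pyrotinib", "capecitabine"))
                     .doseTarget[[drug]]
                   else .doseTarget[[drug]],
             stringsAsFactors = FALSE)
}

## deSolve event table (indices into the canonical state vector)
.asSolverEvents <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  if (!all(events$var %in% names(stateTemplate())))
    stop("unknown dose target state", call. = FALSE)
  ev <- data.frame(var = events$var, time = events$time,
                   value = events$amount, method = "add",
                   stringsAsFactors = FALSE)
  ev[order(ev$time), ]
}

#' Simulate plasma pharmacokinetics
#'
#' Runs the compartmental PK model of one drug for a schedule of dose
#' events and returns per-compartment amounts and central concentration.
#' IV doses enter the central compartment as boluses, oral doses via
#' first-order absorption. The full system is linear, so dose
#' proportionality and superposition hold.
#'
#' @param params a \code{\link{pkParams}} record.
#' @param events a \code{\link{doseEvents}} table (times sorted).
#' @param duration hours.
#' @param dt output step (h).
#' @param atol,rtol solver tolerances.
#' @return data.frame with time (h), per-compartment amounts (mg) and
#'   \code{conc} = central concentration (mg/L).
#' @export
simulatePK <- function(params, events, duration, dt = 0.5, atol = 1e-10,
                       rtol = 1e-10) {
  drug <- params$drug
  if (!is.null(events) && nrow(events) &&
      !all(events$drug == drug))
    stop("events refer to a different drug than 'params'", call. = FALSE)
  p <- .assembleParams(cellLineConfig("SKBR3"), signalingParams(),
                       drugs = drug, mechanisms = NULL, pk = list(params),
                       inVitro = FALSE)
  y0 <- stateTemplate()
  y0[c("E1", "E2", "E3", "E4", "PI3K", "AKT", "RAF", "ERK")] <- 0
  y0["NCELL"] <- 0
  times <- sort(unique(round(c(seq(0, duration, by = dt),
                               events$time[events$time <= duration]), 6)))
  states <- .solve(y0, times, p, events = .asSolverEvents(events),
                   atol = atol, rtol = rtol)
  comp <- switch(drug,
    lapatinib = c("GLAP", "CLAPC", "CLAPP"),
    pyrotinib = c("GPYR", "CPYRC", "CPYRP"),
    tdm1 = c("A1C", "A1P", "PL1C", "PL1P"),
    tdxd = c("A2C", "A2P", "PL2C", "PL2P"),
    capecitabine = c("GCAP", "ACAP", "DFCR", "DFUR", "AFU"))
  out <- data.frame(time = times, states[, comp, drop = FALSE])
  Vc <- switch(drug, lapatinib = p[["lap_Vc"]], pyrotinib = p[["pyr_Vc"]],
               tdm1 = p[["tdm1_Vc"]], tdxd = p[["tdxd_Vc"]],
               capecitabine = p[["cap_V"]])
  central <- switch(drug, lapatinib = "CLAPC", pyrotinib = "CPYRC",
                    tdm1 = "A1C", tdxd = "A2C", capecitabine = "ACAP")
  out$conc <- out[[central]] / Vc
  attr(out, "drug") <- drug
  attr(out, "params") <- params
  out
}

#' Simulate the capecitabine metabolite cascade
#'
#' Oral capecitabine is sequentially converted to 5'DFCR, 5'DFUR and the
#' tumoricidal 5-FU by first-order steps; each metabolite peaks at or after
#' its precursor.
#'
#' @param params \code{\link{pkParams}("capecitabine")}.
#' @param events oral dose events.
#' @param duration hours.
#' @param dt output step (h).
#' @param atol,rtol solver tolerances.
#' @return data.frame of time and concentrations (mg/L) of parent and
#'   metabolites.
#' @export
capecitabineCascade <- function(params, events, duration, dt = 0.1,
                                atol = 1e-10, rtol = 1e-10) {
  stopifnot(params$drug == "capecitabine")
  if (!is.null(events) && nrow(events) && any(events$route != "oral"))
    stop("capecitabine is dosed orally", call. = FALSE)
  tab <- simulatePK(params, events, duration, dt, atol = atol,
                    rtol = rtol)
  Vc <- params$V * params$bw
  Vm <- params$Vmet * params$bw
  data.frame(time = tab$time,
             capecitabine = tab$ACAP / Vc,
             dfcr = tab$DFCR / Vm,
             dfur = tab$DFUR / Vm,
             fu = tab$AFU / Vm)
}

#' Tumor exposure from a plasma profile
#'
#' Applies the drug's tumor-coupling mode: instantaneous partitioning
#' (tumor concentration = Kp x central concentration) for TKIs and
#' capecitabine/5-FU, or first-order tumor entry (influx = k_tu x central
#' amount, no back-flux, first-order tumor loss) for the ADCs.
#'
#' @param plasma a \code{\link{simulatePK}} result covering the horizon.
#' @param params the matching \code{\link{pkParams}} record.
#' @return data.frame with time and \code{tumor} (nM for ADC, mg/L scale
#'   for Kp drugs); for ADCs also \code{influx_cum}, the cumulative entry.
#' @export
tumorExposure <- function(plasma, params) {
  drug <- params$drug
  if (!identical(attr(plasma, "drug"), drug))
    stop("plasma table was generated for a different drug", call. = FALSE)
  t <- plasma$time
  if (drug %in% c("lapatinib", "pyrotinib", "capecitabine")) {
    if (is.null(params$Kp))
      stop("missing tumor partition coefficient Kp", call. = FALSE)
    src <- if (drug == "capecitabine") plasma$AFU / (params$Vmet * params$bw)
           else plasma$conc
    return(data.frame(time = t, tumor = params$Kp * src))
  }
  if (is.null(params$k_tu))
    stop("missing ADC tumor entry rate k_tu", call. = FALSE)
  amt <- if (drug == "tdm1") plasma$A1C else plasma$A2C
  influx <- params$k_tu * amt
  ## integrate dT/dt = influx - kelim_tu * T on the output grid
  ## (exponential-Euler update)
  tumor <- numeric(length(t))
  cum <- numeric(length(t))
  for (i in seq_along(t)[-1]) {
    dtstep <- t[i] - t[i - 1]
    f <- 0.5 * (influx[i] + influx[i - 1])
    decay <- exp(-params$kelim_tu * dtstep)
    tumor[i] <- tumor[i - 1] * decay +
      f / params$kelim_tu * (1 - decay)
    cum[i] <- cum[i - 1] + f * dtstep
  }
  data.frame(time = t, tumor = tumor, influx_cum = cum)
}
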