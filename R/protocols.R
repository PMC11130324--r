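## Simulated experimental protocols: viability assays, xenograft studies,
## regimen expansion, readout normalization and TGI.

#' Construct a treatment regimen
#'
#' A regimen is a list of arms; each arm is a drug with a dose (mg/kg in
#' vivo), a schedule tag and a route. Supported schedule tags (21-day
#' cycles): "qd" (daily), "q3w" (day 1 of each cycle), "d1-d14" (days 1-14
#' of each cycle), "single" (one dose at start), "custom" (explicit
#' \code{days}).
#'
#' @param ... arm records created by \code{regimenArm}, or a single list of
#'   them.
#' @return a \code{\linkS4class{Regimen}}; with no arms, a control regimen.
#' @examples
#' regimen(regimenArm("pyrotinib", 6, "qd"),
#'         regimenArm("tdm1", 6, "q3w"))
#' @export
regimen <- function(...) {
  arms <- list(...)
  if (length(arms) == 1L && is.list(arms[[1]]) && is.null(arms[[1]]$drug))
    arms <- arms[[1]]
  new("Regimen", arms = arms)
}

#' @rdname regimen
#' @param drug drug name.
#' @param dose mg/kg per administration.
#' @param schedule schedule tag.
#' @param route "oral" or "iv" (defaults to the drug's clinical route).
#' @param start start day of treatment (day 0 = first treatment day).
#' @param days explicit dosing days for \code{schedule = "custom"}.
#' @export
regimenArm <- function(drug, dose, schedule = c("qd", "q3w", "d1-d14",
                                                "single", "custom"),
                       route = NULL, start = 0, days = NULL) {
  drug <- match.arg(drug, names(.doseTarget))
  schedule <- match.arg(schedule)
  .assertScalarNum(dose, "dose", lower = 0)
  if (is.null(route)) route <- .defaultRoute[[drug]]
  if (schedule == "custom" && is.null(days))
    stop("schedule 'custom' requires explicit 'days'", call. = FALSE)
  list(drug = drug, dose = dose, schedule = schedule, route = route,
       start = start, days = days)
}

#' Expand a regimen into a dose-event table
#'
#' Deterministic, order-independent expansion of schedule tags into
#' per-administration dose events over the follow-up window (21-day cycle
#' length for "d1-d14" and "q3w").
#'
#' @param reg a \code{\linkS4class{Regimen}}.
#' @param followUpDays length of the study window in days.
#' @param bw body weight (kg).
#' @return a dose-event data.frame (see \code{\link{doseEvents}}), sorted
#'   by time then drug.
#' @export
expandRegimen <- function(reg, followUpDays, bw = 0.02) {
  stopifnot(is(reg, "Regimen"))
  evs <- lapply(reg@arms, function(a) {
    days <- switch(a$schedule,
      qd = seq(a$start, followUpDays - 1, by = 1),
      q3w = seq(a$start, followUpDays - 1, by = 21),
      `d1-d14` = {
        starts <- seq(a$start, followUpDays - 1, by = 21)
        unlist(lapply(starts, function(s) s + 0:13))
      },
      single = a$start,
      custom = a$days)
    days <- days[days >= 0 & days < followUpDays]
    if (!length(days)) return(NULL)
    doseEvents(a$drug, a$dose, times = days * 24, route = a$route, bw = bw)
  })
  evs <- do.call(rbind, evs[!vapply(evs, is.null, TRUE)])
  if (is.null(evs))
    return(data.frame(drug = character(), time = numeric(),
                      amount = numeric(), route = character(),
                      var = character(), stringsAsFactors = FALSE))
  evs <- evs[order(evs$time, evs$drug), ]
  rownames(evs) <- NULL
  evs
}

#' Run a simulated dose-viability assay
#'
#' Exposes cells (from their untreated steady state) to a constant drug
#' bath for \code{duration} hours and reports viability as treated cell
#' count divided by the untreated cell count at the same elapsed time, the
#' convention used for densitometry-normalized viability data. Viability
#' can exceed 1 under growth-promoting stimuli (e.g. NRG1).
#'
#' @param network an in vitro \code{\link{buildNetwork}} result.
#' @param drug one of "lapatinib", "pyrotinib", "tdm1", "tdxd", "fu"
#'   (5-FU substitutes for capecitabine in vitro).
#' @param doses concentration grid in nM (may include 0).
#' @param duration exposure in hours (48-168 h typical).
#' @param stim0 base stimulus applied to every arm including control
#'   (e.g. an NRG1 bath).
#' @return data.frame(dose, viability).
#' @export
runViability <- function(network, drug, doses, duration = 72,
                         stim0 = stimulus()) {
  drug <- match.arg(drug, c("lapatinib", "pyrotinib", "tdm1", "tdxd",
                            "fu"))
  stopifnot(length(doses) >= 1)
  ss <- initializeSteadyState(network)
  nEnd <- function(stim) {
    tr <- simulateTimecourse(network, ss, stim, duration, dt = duration / 24)
    ro <- readout(tr, "ncell")
    ro[length(ro)]
  }
  ctrl <- nEnd(stim0)
  viab <- vapply(doses, function(d) {
    stim <- stim0
    stim[[drug]] <- stim[[drug]] + d
    nEnd(stim) / ctrl
  }, 0)
  data.frame(dose = doses, viability = viab)
}

#' Run a simulated xenograft study
#'
#' Simulates tumor growth from the start volume (dosing begins at day 0,
#' when the tumor has reached the start volume) under a regimen whose dose
#' events drive the PK modules; tumor drug exposures couple to the cell
#' model, and volume follows the logistic-capped growth/death law
#' (maximum 2000 mm3 by default).
#'
#' @param network an in vivo network (\code{buildNetwork(..., inVitro =
#'   FALSE)} with in vivo growth parameters).
#' @param reg a \code{\linkS4class{Regimen}} (empty = control arm).
#' @param followUpDays study length in days.
#' @param startVolume tumor volume at treatment day 0 (mm3, default 80).
#' @param stim0 optional stimulus overrides (e.g. constant NRG1 bath).
#' @param bw body weight (kg).
#' @param outputDt output cadence in days.
#' @return data.frame(day, volume) with attribute "trajectory".
#' @export
runXenograft <- function(network, reg = regimen(), followUpDays = 21,
                         startVolume = 80, stim0 = stimulus(), bw = 0.02,
                         outputDt = 1) {
  stopifnot(network@params[["f_invitro"]] == 0)
  missingPk <- setdiff(unique(vapply(reg@arms, `[[`, "", "drug")),
                       network@drugs)
  if (length(missingPk))
    stop("regimen drug(s) without wired PK: ",
         paste(missingPk, collapse = ", "), call. = FALSE)
  ss <- initializeSteadyState(network)
  app <- .applyStimulus(network@params, ss, stim0)
  y0 <- app$y0
  y0["NCELL"] <- startVolume * network@params[["cells_per_mm3"]]
  evs <- expandRegimen(reg, followUpDays, bw = bw)
  evs$time <- round(evs$time, 6)
  grid <- round(seq(0, followUpDays * 24, by = outputDt * 24), 6)
  times <- sort(unique(c(grid, evs$time)))
  states <- .solve(y0, times, app$params, events = .asSolverEvents(evs),
                   atol = 1e-6, rtol = 1e-6)
  keep <- times %in% grid
  vol <- states[keep, "NCELL"] / network@params[["cells_per_mm3"]]
  out <- data.frame(day = times[keep] / 24, volume = vol)
  attr(out, "trajectory") <- new("Trajectory", times = times,
                                 states = states,
                                 inputs = list(stimulus = stim0,
                                               params = app$params,
                                               events = evs))
  out
}

#' Tumor growth inhibition
#'
#' Baseline-corrected TGI (default): \code{100 (1 - (V_t(day) - V0) /
#' (V_c(day) - V0))}, clipped at 100 so that full regression to baseline
#' scores 100. The ratio-of-volumes form \code{100 (1 - V_t/V_c)} is also
#' available.
#'
#' @param treated,control volume series as data.frame(day, volume) from
#'   \code{\link{runXenograft}}.
#' @param day evaluation day (must be covered by both series).
#' @param baselineCorrected logical; use the baseline-corrected form.
#' @return TGI in percent (<= 100; negative when treated grows faster).
#' @export
computeTGI <- function(treated, control, day,
                       baselineCorrected = TRUE) {
  vAt <- function(series, d) {
    if (d < min(series$day) || d > max(series$day))
      stop("series does not cover day ", d, call. = FALSE)
    stats::approx(series$day, series$volume, xout = d)$y
  }
  v0t <- vAt(treated, min(treated$day))
  v0c <- vAt(control, min(control$day))
  vt <- vAt(treated, day)
  vc <- vAt(control, day)
  if (baselineCorrected) {
    if (vc <= v0c)
      stop("control arm has not grown beyond baseline; TGI undefined",
           call. = FALSE)
    min(100, 100 * (1 - (vt - v0t) / (vc - v0c)))
  } else {
    if (vc <= 0) stop("control volume is zero; TGI undefined",
                      call. = FALSE)
    min(100, 100 * (1 - vt / vc))
  }
}

#' Normalize a readout series
#'
#' Densitometry-style normalization: to the series maximum
#' (\code{mode = "max"}) or to a control point (\code{mode = "control"}).
#'
#' @param series numeric vector.
#' @param mode "max" or "control".
#' @param controlIndex index of the control point for
#'   \code{mode = "control"}.
#' @return normalized series.
#' @export
normalizeReadout <- function(series, mode = c("max", "control"),
                             controlIndex = 1L) {
  mode <- match.arg(mode)
  ref <- switch(mode, max = max(series), control = series[[controlIndex]])
  if (!is.finite(ref) || ref <= 0)
    stop("normalization reference must be > 0", call. = FALSE)
  series / ref
}
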