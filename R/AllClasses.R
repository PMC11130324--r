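#' @import methods
NULL

## ---------------------------------------------------------------------------
## CellLineConfig

#' CellLineConfig: receptor abundances and growth behavior of a cell line
#'
#' Holds ErbB receptor copy numbers (molecules/cell), the HER2
#' immunohistochemistry level and the growth/death parameter record for one
#' cell line.
#'
#' @slot name cell line name.
#' @slot receptors named numeric: EGFR, HER2, HER3, HER4 copies per cell.
#' @slot ihc IHC grade ("1+", "2+", "3+").
#' @slot growth growth/death parameter list (see
#'   \code{\link{growthDeathParams}}).
#' @export
setClass("CellLineConfig",
  representation(name = "character", receptors = "numeric",
                 ihc = "character", growth = "list"),
  validity = function(object) {
    msg <- NULL
    need <- c("EGFR", "HER2", "HER3", "HER4")
    if (!identical(sort(names(object@receptors)), sort(need)))
      msg <- c(msg, "receptors must be named EGFR, HER2, HER3, HER4")
    else if (any(object@receptors < 0) || any(!is.finite(object@receptors)))
      msg <- c(msg, "receptor counts must be finite and >= 0")
    if (!object@ihc %in% c("0", "1+", "2+", "3+"))
      msg <- c(msg, "ihc must be one of '0', '1+', '2+', '3+'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a cell line configuration
#'
#' @param name cell line name; the presets "SKBR3", "BT474", "NCI-N87" and
#'   "ZR75-1" fill receptor numbers from quantitative literature
#'   measurements (SKBR3: EGFR 150,000; HER2 1,500,000; HER3 40,000;
#'   HER4 2,000) or from the IHC-level convention (3+ = 1.5e6, 2+ = 0.5e6,
#'   1+ = 0.1e6 HER2/cell).
#' @param receptors optional named numeric vector overriding the preset.
#' @param ihc optional IHC grade override.
#' @param growth growth/death parameter list.
#' @return a \code{CellLineConfig}.
#' @examples
#' cellLineConfig("SKBR3")
#' cellLineConfig("custom", receptors = c(EGFR = 1e5, HER2 = 5e5,
#'                                        HER3 = 2e4, HER4 = 1e3),
#'                ihc = "2+")
#' @export
cellLineConfig <- function(name, receptors = NULL, ihc = NULL,
                           growth = growthDeathParams()) {
  presets <- list(
    SKBR3 = list(rec = c(EGFR = 150000, HER2 = 1.5e6, HER3 = 40000,
                         HER4 = 2000), ihc = "3+"),
    BT474 = list(rec = c(EGFR = 100000, HER2 = 1.5e6, HER3 = 30000,
                         HER4 = 2000), ihc = "3+"),
    `NCI-N87` = list(rec = c(EGFR = 100000, HER2 = 0.5e6, HER3 = 30000,
                             HER4 = 2000), ihc = "2+"),
    `ZR75-1` = list(rec = c(EGFR = 100000, HER2 = 0.1e6, HER3 = 30000,
                            HER4 = 2000), ihc = "1+"))
  if (is.null(receptors)) {
    if (!name %in% names(presets))
      stop("unknown cell line '", name, "'; supply 'receptors' or use one ",
           "of: ", paste(names(presets), collapse = ", "), call. = FALSE)
    receptors <- presets[[name]]$rec
    if (is.null(ihc)) ihc <- presets[[name]]$ihc
  }
  if (is.null(ihc)) ihc <- "3+"
  bad <- setdiff(names(receptors), c("EGFR", "HER2", "HER3", "HER4"))
  if (length(bad))
    stop("unknown receptor name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  new("CellLineConfig", name = name, receptors = receptors, ihc = ihc,
      growth = growth)
}

#' HER2 IHC-level preset
#'
#' Returns a cell line configuration whose HER2 copy number follows the
#' IHC convention: 3+ = 1.5e6, 2+ = 0.5e6, 1+ = 0.1e6 HER2/cell. The
#' growth-signal half-saturation (km13) is recalibrated per level so that
#' each line proliferates at its own (lower) baseline signaling tone, the
#' same per-line re-estimation of growth parameters used for cell lines
#' with different HER2 expression.
#'
#' @param level "1+", "2+" or "3+".
#' @param inVivo logical; use the in vivo growth/death rates.
#' @param ... growth/death parameter overrides.
#' @export
ihcPreset <- function(level = c("3+", "2+", "1+"), inVivo = FALSE, ...) {
  level <- match.arg(level)
  her2 <- switch(level, "3+" = 1.5e6, "2+" = 0.5e6, "1+" = 0.1e6)
  km13 <- switch(level, "3+" = 0.5, "2+" = 0.10, "1+" = 0.07)
  cellLineConfig(paste0("IHC", level),
                 receptors = c(EGFR = 100000, HER2 = her2, HER3 = 30000,
                               HER4 = 2000),
                 ihc = level,
                 growth = growthDeathParams(inVivo = inVivo, km13 = km13,
                                            ...))
}

setMethod("show", "CellLineConfig", function(object) {
  cat("CellLineConfig '", object@name, "' (IHC ", object@ihc, ")\n",
      sep = "")
  cat("  receptors/cell:",
      paste(names(object@receptors),
            format(object@receptors, big.mark = ","), collapse = "; "),
      "\n")
})

#' @describeIn cellLineConfig receptor copy numbers accessor
#' @param object a \code{CellLineConfig}.
#' @export
setGeneric("receptorCounts", function(object) standardGeneric("receptorCounts"))

#' @export
setMethod("receptorCounts", "CellLineConfig",
          function(object) object@receptors)

## ---------------------------------------------------------------------------
## ReactionNetwork

#' ReactionNetwork: species, reactions and stoichiometry of the model
#'
#' The symbolic form of the ODE system: an ordered species table, a list of
#' reactions (each with reactants, products, a rate-law tag and a rate
#' function), and the species-by-reaction stoichiometry matrix. The compiled
#' right-hand side is checked against a naive per-reaction interpretation of
#' this object.
#'
#' @slot species data.frame with columns name, unit, initial.
#' @slot reactions list of reaction records.
#' @slot stoichiometry species x reactions integer matrix.
#' @slot params named numeric parameter vector.
#' @slot cellLine the originating \code{CellLineConfig}.
#' @slot drugs character vector of wired drugs.
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "list",
                 stoichiometry = "matrix", params = "numeric",
                 cellLine = "CellLineConfig", drugs = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@species) > 60)
      msg <- c(msg, "species budget exceeded (> 60)")
    if (length(object@reactions) > 80)
      msg <- c(msg, "reaction budget exceeded (> 80)")
    if (!identical(dim(object@stoichiometry),
                   c(nrow(object@species), length(object@reactions))))
      msg <- c(msg, "stoichiometry dimensions do not match species/reactions")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork:", nrow(object@species), "species,",
      length(object@reactions), "reactions\n")
  cat("  cell line:", object@cellLine@name, "| drugs:",
      if (length(object@drugs)) paste(object@drugs, collapse = ", ")
      else "(none)", "\n")
})

#' @rdname speciesNames
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' Species names of a reaction network
#' @param object a \code{ReactionNetwork}.
#' @return character vector of species names in canonical order.
#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ReactionNetwork",
          function(object) object@species$name)

#' @rdname reactionCount
#' @export
setGeneric("reactionCount", function(object) standardGeneric("reactionCount"))

#' Number of reactions in a network
#' @param object a \code{ReactionNetwork}.
#' @rdname reactionCount
#' @export
setMethod("reactionCount", "ReactionNetwork",
          function(object) length(object@reactions))

#' @rdname networkParams
#' @export
setGeneric("networkParams", function(object) standardGeneric("networkParams"))

#' Parameter vector of a network
#' @param object a \code{ReactionNetwork}.
#' @rdname networkParams
#' @export
setMethod("networkParams", "ReactionNetwork",
          function(object) object@params)

## ---------------------------------------------------------------------------
## Trajectory

#' Trajectory: a simulated time course
#'
#' Time-indexed state matrix plus the stimulus record that produced it.
#' Readouts (pEGFR, pHER2, pHER3, pHER4, pAKT, pERK, receptor totals, cell
#' count, tumor volume) are extracted with \code{\link{readout}}.
#'
#' @slot times numeric vector (hours), strictly increasing.
#' @slot states times x species matrix.
#' @slot inputs the stimulus record used.
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", inputs = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != nrow(object@states))
      msg <- c(msg, "length(times) must equal nrow(states)")
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "time points over",
      round(max(object@times), 2), "h;", ncol(object@states), "species\n")
})

#' @rdname trajTimes
#' @export
setGeneric("trajTimes", function(object) standardGeneric("trajTimes"))

#' Time grid of a trajectory (hours)
#' @param object a \code{Trajectory}.
#' @rdname trajTimes
#' @export
setMethod("trajTimes", "Trajectory", function(object) object@times)

#' @rdname trajStates
#' @export
setGeneric("trajStates", function(object) standardGeneric("trajStates"))

#' State matrix of a trajectory
#' @param object a \code{Trajectory}.
#' @rdname trajStates
#' @export
setMethod("trajStates", "Trajectory", function(object) object@states)

## ---------------------------------------------------------------------------
## Regimen

#' Regimen: a schedule of dose events
#'
#' A set of treatment arms, each a drug with a dose (mg/kg in vivo), a
#' schedule tag (qd, q3w, d1-d14, single, or a custom event list) and a
#' route. Schedule tags expand deterministically to dose-event tables on a
#' 21-day cycle.
#'
#' @slot arms list of arm records.
#' @export
setClass("Regimen", representation(arms = "list"))

setMethod("show", "Regimen", function(object) {
  if (!length(object@arms)) {
    cat("Regimen: (control, no treatment)\n")
    return(invisible(NULL))
  }
  cat("Regimen with", length(object@arms), "arm(s):\n")
  for (a in object@arms)
    cat(sprintf("  %s %g mg/kg %s (%s), start day %g\n", a$drug, a$dose,
                a$schedule, a$route, a$start))
})

## ---------------------------------------------------------------------------
## CalibrationDataset

#' CalibrationDataset: observed datapoints with normalization semantics
#'
#' A table of datapoints (condition id, readout, time, dose, mean,
#' dispersion, n, normalization mode) plus a source tag separating
#' calibration from validation data.
#'
#' @slot points data.frame of datapoints.
#' @slot source "calibration" or "validation".
#' @export
setClass("CalibrationDataset",
  representation(points = "data.frame", source = "character"),
  validity = function(object) {
    need <- c("condition", "readout", "time", "mean", "sd", "n", "norm")
    miss <- setdiff(need, names(object@points))
    if (length(miss))
      return(paste("points is missing column(s):",
                   paste(miss, collapse = ", ")))
    if (any(object@points$sd <= 0, na.rm = TRUE))
      return("dispersion (sd) must be > 0 after imputation")
    TRUE
  })

setMethod("show", "CalibrationDataset", function(object) {
  cat("CalibrationDataset (", object@source, "): ", nrow(object@points),
      " points, ", length(unique(object@points$condition)),
      " condition(s)\n", sep = "")
})

#' @rdname datasetPoints
#' @export
setGeneric("datasetPoints", function(object) standardGeneric("datasetPoints"))

#' Datapoint table of a calibration dataset
#' @param object a \code{CalibrationDataset}.
#' @rdname datasetPoints
#' @export
setMethod("datasetPoints", "CalibrationDataset",
          function(object) object@points)

## ---------------------------------------------------------------------------
## Phenotype

#' Phenotype: a named parameter-override preset
#'
#' Parameter multipliers / absolute overrides plus stimulus overrides
#' (e.g. a constant NRG1 bath) that turn the calibrated baseline into one of
#' the heterogeneous response phenotypes.
#'
#' @slot name preset name.
#' @slot multipliers named numeric multipliers on baseline parameters.
#' @slot absolutes named numeric absolute parameter overrides.
#' @slot stimuli named numeric stimulus overrides (nM baths).
#' @export
setClass("Phenotype",
  representation(name = "character", multipliers = "numeric",
                 absolutes = "numeric", stimuli = "numeric"))

setMethod("show", "Phenotype", function(object) {
  cat("Phenotype '", object@name, "'\n", sep = "")
  if (length(object@multipliers))
    cat("  multipliers:",
        paste(names(object@multipliers), object@multipliers, sep = " x",
              collapse = ", "), "\n")
  if (length(object@absolutes))
    cat("  absolutes:",
        paste(names(object@absolutes), object@absolutes, sep = " = ",
              collapse = ", "), "\n")
  if (length(object@stimuli))
    cat("  stimuli:",
        paste(names(object@stimuli), object@stimuli, sep = " = ",
              collapse = ", "), "nM\n")
})

## ---------------------------------------------------------------------------
## SynergySurface

#' SynergySurface: Bliss classification over a dose grid
#'
#' Model-simulated fractional effects, Bliss-expected effects and the
#' per-cell synergy classification over a two-drug dose grid.
#'
#' @slot doses_a,doses_b dose vectors.
#' @slot model_effect,bliss_effect effect matrices in [0, 1].
#' @slot classification character matrix ("synergistic", "additive",
#'   "antagonistic", "undefined").
#' @export
setClass("SynergySurface",
  representation(doses_a = "numeric", doses_b = "numeric",
                 model_effect = "matrix", bliss_effect = "matrix",
                 classification = "matrix"),
  validity = function(object) {
    d <- c(length(object@doses_a), length(object@doses_b))
    for (m in list(object@model_effect, object@bliss_effect,
                   object@classification))
      if (!identical(dim(m), as.integer(d)))
        return("matrices must be doses_a x doses_b")
    eff <- c(object@model_effect, object@bliss_effect)
    eff <- eff[is.finite(eff)]
    if (length(eff) && (min(eff) < 0 || max(eff) > 1))
      return("effects must lie in [0, 1]")
    TRUE
  })

setMethod("show", "SynergySurface", function(object) {
  tab <- table(factor(object@classification,
                      levels = c("synergistic", "additive", "antagonistic",
                                 "undefined")))
  cat("SynergySurface ", length(object@doses_a), "x",
      length(object@doses_b), ": ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})
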