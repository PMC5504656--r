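#' @import methods
#' @importFrom Rcpp sourceCpp evalCpp
#' @useDynLib tnbcABM, .registration = TRUE
NULL

## Integer codes shared between the R surface and the C++ engine.
## Cell table columns: i, j, k (0-based voxel), lineage, ccr5, divisions, state.
.CELL_COLS <- c("i", "j", "k", "lineage", "ccr5", "divisions", "state")
.LINEAGE_STEM <- 0L
.LINEAGE_PROG <- 1L
.CCR5_LOW <- 0L
.CCR5_HIGH <- 1L
.STATE_PROLIF <- 0L
.STATE_QUIESCENT <- 1L
.STATE_SENESCENT <- 2L

#' Pulsed dosing schedule for the anti-stem-cell drug
#'
#' Doses are applied at the start of each dosing day, before the daily
#' cell sweep. Each dose independently kills every stem cell with
#' probability \code{efficacy}; progenitor cells are untouched.
#'
#' @slot startDay integer; first dosing day.
#' @slot intervalDays integer; days between doses (>= 1).
#' @slot endDay integer; last day on which a dose may fall.
#' @slot efficacy numeric in [0, 1]; per-dose stem-cell kill probability.
#'
#' @seealso [doseSchedule()], [doseDays()], [applyAntiStemDose()]
#' @export
setClass("DoseSchedule",
  representation(
    startDay = "integer",
    intervalDays = "integer",
    endDay = "integer",
    efficacy = "numeric"
  )
)

setValidity("DoseSchedule", function(object) {
  msg <- character()
  if (length(object@startDay) != 1L || is.na(object@startDay))
    msg <- c(msg, "startDay must be a single integer")
  if (length(object@intervalDays) != 1L || is.na(object@intervalDays) ||
      object@intervalDays < 1L)
    msg <- c(msg, "intervalDays must be >= 1")
  if (length(object@endDay) != 1L || is.na(object@endDay))
    msg <- c(msg, "endDay must be a single integer")
  if (length(object@efficacy) != 1L || is.na(object@efficacy) ||
      object@efficacy < 0 || object@efficacy > 1)
    msg <- c(msg, "efficacy must be a probability in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Parameters of the lattice tumor model
#'
#' All per-day stochastic rates, lattice geometry, hypoxia settings,
#' intervention switches, and stopping rules of the model. Construct
#' with [tumorParams()], which supplies the MDA-MB-231 reference values
#' as defaults.
#'
#' @slot pProlifStem daily division probability of a stem cell.
#' @slot pProlifProg daily division probability of a progenitor cell.
#' @slot pSymmetric probability that a stem division is symmetric
#'   (stem + stem) rather than asymmetric (stem + progenitor).
#' @slot pCcr5Convert probability that the daughter of a symmetric
#'   division is CCR5-high under normoxia.
#' @slot pCcr5ConvertHypoxic the same conversion probability in hypoxia.
#' @slot divisionLimit number of divisions a progenitor may undergo
#'   before senescence.
#' @slot pSenescentDeath daily death probability of a senescent cell.
#' @slot stepsCcr5Low,stepsCcr5High migration speed in voxel steps per
#'   day for CCR5-low and CCR5-high cells under normoxia.
#' @slot maxStepsPerDay hard cap on daily voxel steps.
#' @slot hypoxiaMigrationFactor multiplier on steps per day in hypoxia.
#' @slot hypoxiaProlifFactor multiplier on division probability in hypoxia.
#' @slot hypoxiaDistance distance from the vessel (micrometres) beyond
#'   which a voxel is hypoxic (strict inequality).
#' @slot hypoxiaOn logical; enable geometric hypoxia.
#' @slot vesselKind "plane" or "line"; static vessel geometry.
#' @slot vesselAnchor integer voxel coordinates anchoring the geometry.
#' @slot vesselAxis axis label ("x", "y" or "z"); for a plane, the plane
#'   is perpendicular to this axis and passes through the anchor; for a
#'   line, the line runs along this axis through the anchor.
#' @slot maravirocOn logical; continuous CCR5 inhibition (CCR5-high cells
#'   migrate at the CCR5-low speed).
#' @slot antiStem a [DoseSchedule-class] or \code{NULL}.
#' @slot initCounts integer quadruple: initial numbers of stem/CCR5-low,
#'   stem/CCR5-high, progenitor/CCR5-high, progenitor/CCR5-low cells.
#' @slot dims integer triple; lattice size in voxels.
#' @slot voxelSize voxel edge length, micrometres.
#' @slot seedOffset distance (voxels) from the vessel to the nearest face
#'   of the cubic seeding block.
#' @slot seedSize edge length (voxels) of the seeding block.
#' @slot senescentMigrate logical; whether senescent cells still migrate.
#' @slot maxDays,maxCells stopping rules: last simulated day, and the
#'   population size at which a run stops (checked at day end).
#' @slot seed integer seed for the run's random stream.
#'
#' @seealso [tumorParams()], [runSimulation()]
#' @export
setClass("TumorParams",
  representation(
    pProlifStem = "numeric",
    pProlifProg = "numeric",
    pSymmetric = "numeric",
    pCcr5Convert = "numeric",
    pCcr5ConvertHypoxic = "numeric",
    divisionLimit = "integer",
    pSenescentDeath = "numeric",
    stepsCcr5Low = "integer",
    stepsCcr5High = "integer",
    maxStepsPerDay = "integer",
    hypoxiaMigrationFactor = "numeric",
    hypoxiaProlifFactor = "numeric",
    hypoxiaDistance = "numeric",
    hypoxiaOn = "logical",
    vesselKind = "character",
    vesselAnchor = "integer",
    vesselAxis = "character",
    maravirocOn = "logical",
    antiStem = "ANY",
    initCounts = "integer",
    dims = "integer",
    voxelSize = "numeric",
    seedOffset = "integer",
    seedSize = "integer",
    senescentMigrate = "logical",
    maxDays = "integer",
    maxCells = "integer",
    seed = "integer"
  )
)

setValidity("TumorParams", function(object) {
  msg <- character()
  probs <- c(
    pProlifStem = object@pProlifStem, pProlifProg = object@pProlifProg,
    pSymmetric = object@pSymmetric, pCcr5Convert = object@pCcr5Convert,
    pCcr5ConvertHypoxic = object@pCcr5ConvertHypoxic,
    pSenescentDeath = object@pSenescentDeath
  )
  bad <- names(probs)[is.na(probs) | probs < 0 | probs > 1]
  if (length(bad))
    msg <- c(msg, paste0("probabilities outside [0, 1]: ",
                         paste(bad, collapse = ", ")))
  if (object@divisionLimit < 0L)
    msg <- c(msg, "divisionLimit must be non-negative")
  if (object@stepsCcr5Low < 0L || object@stepsCcr5High < 0L)
    msg <- c(msg, "migration steps must be non-negative")
  if (object@maxStepsPerDay < 1L)
    msg <- c(msg, "maxStepsPerDay must be >= 1")
  if (object@hypoxiaMigrationFactor < 0 || object@hypoxiaProlifFactor < 0)
    msg <- c(msg, "hypoxia factors must be non-negative")
  if (object@hypoxiaDistance < 0)
    msg <- c(msg, "hypoxiaDistance must be non-negative")
  if (length(object@initCounts) != 4L || any(object@initCounts < 0L))
    msg <- c(msg, "initCounts must be 4 non-negative integers")
  if (sum(object@initCounts) < 1L)
    msg <- c(msg, "initCounts must sum to at least 1")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be 3 positive integers")
  if (object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be positive")
  if (!object@vesselKind %in% c("plane", "line"))
    msg <- c(msg, "vesselKind must be 'plane' or 'line'")
  if (!object@vesselAxis %in% c("x", "y", "z"))
    msg <- c(msg, "vesselAxis must be 'x', 'y' or 'z'")
  if (length(object@vesselAnchor) != 3L)
    msg <- c(msg, "vesselAnchor must be 3 integers")
  if (object@seedOffset < 0L || object@seedSize < 1L)
    msg <- c(msg, "seedOffset must be >= 0 and seedSize >= 1")
  if (object@maxDays < 0L) msg <- c(msg, "maxDays must be non-negative")
  if (object@maxCells < 1L) msg <- c(msg, "maxCells must be positive")
  if (!is.null(object@antiStem) && !is(object@antiStem, "DoseSchedule"))
    msg <- c(msg, "antiStem must be NULL or a DoseSchedule")
  if (length(msg)) msg else TRUE
})

#' State of a running tumor simulation
#'
#' Holds the cell table, the current day, the accumulated per-day time
#' series, and (when hypoxia is enabled) the precomputed per-voxel
#' hypoxia field. Create with [initPopulation()] or [simFromCells()];
#' advance with [stepDay()] or run to completion with [runSimulation()].
#'
#' @slot day integer; current simulated day.
#' @slot cells integer matrix with columns i, j, k (0-based voxel
#'   coordinates), lineage (0 = stem, 1 = progenitor), ccr5 (0 = low,
#'   1 = high), divisions, state (0 = proliferative, 1 = quiescent,
#'   2 = senescent); one row per live cell.
#' @slot params the [TumorParams-class] governing the run.
#' @slot hypoxic logical vector of length \code{prod(dims)} (column-major
#'   voxel order), or length 0 when hypoxia is disabled.
#' @slot log data.frame with one row per day (see [timeSeries()]).
#' @slot pendingDeaths integer; deaths applied since the last daily sweep
#'   (e.g. by an anti-stem dose), folded into the next day's record.
#'
#' @seealso [timeSeries()], [cellTable()], [nCells()]
#' @export
setClass("TumorSim",
  representation(
    day = "integer",
    cells = "matrix",
    params = "TumorParams",
    hypoxic = "logical",
    log = "data.frame",
    pendingDeaths = "integer"
  )
)

setValidity("TumorSim", function(object) {
  msg <- character()
  cells <- object@cells
  if (!is.integer(cells) || ncol(cells) != 7L)
    msg <- c(msg, "cells must be an integer matrix with 7 columns")
  if (nrow(cells)) {
    d <- object@params@dims
    pos <- cells[, 1:3, drop = FALSE]
    if (any(pos < 0L) || any(pos[, 1] >= d[1]) || any(pos[, 2] >= d[2]) ||
        any(pos[, 3] >= d[3]))
      msg <- c(msg, "cell positions outside lattice bounds")
    key <- (pos[, 3] * d[2] + pos[, 2]) * d[1] + pos[, 1]
    if (anyDuplicated(key))
      msg <- c(msg, "two cells occupy the same voxel")
    senA <- cells[, 4] == .LINEAGE_PROG &
      cells[, 6] >= object@params@divisionLimit
    if (any(senA & cells[, 7] != .STATE_SENESCENT))
      msg <- c(msg, "progenitor at its division limit must be senescent")
    if (any(cells[, 4] == .LINEAGE_STEM & cells[, 7] == .STATE_SENESCENT))
      msg <- c(msg, "stem cells cannot be senescent")
  }
  if (length(msg)) msg else TRUE
})

#' A voxelized tumor mask
#'
#' The set of occupied voxels of one tumor snapshot, used by the shape
#' metrics. Coordinates are 0-based integers. \code{dims} bounds the
#' lattice: voxels outside it count as occupied (static walls), matching
#' the simulation engine, so a mask that fills its lattice has no
#' free-facing surface.
#'
#' @slot coords integer matrix (n x 3) of occupied voxels, 0-based.
#' @slot dims integer triple; lattice extent.
#' @slot voxelSize voxel edge length in micrometres (metrics are
#'   dimensionless, so this only matters for exported coordinates).
#'
#' @seealso [tumorMask()], [shapeReport()]
#' @export
setClass("TumorMask",
  representation(
    coords = "matrix",
    dims = "integer",
    voxelSize = "numeric"
  )
)

setValidity("TumorMask", function(object) {
  msg <- character()
  if (!is.integer(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an integer matrix with 3 columns")
  if (nrow(object@coords) < 1L)
    msg <- c(msg, "mask must contain at least one voxel")
  if (length(object@dims) != 3L)
    msg <- c(msg, "dims must be 3 integers")
  else if (nrow(object@coords)) {
    if (any(object@coords < 0L) ||
        any(sweep(object@coords, 2, object@dims, ">=")))
      msg <- c(msg, "coords outside dims")
    d <- object@dims
    key <- (object@coords[, 3] * d[2] + object@coords[, 2]) * d[1] +
      object@coords[, 1]
    if (anyDuplicated(key)) msg <- c(msg, "duplicate voxels in mask")
  }
  if (length(msg)) msg else TRUE
})

#' 3D shape metrics of one tumor snapshot
#'
#' Produced by [shapeReport()]. Undefined metrics (single-voxel or
#' zero-variance radial profiles) are reported as \code{NA}.
#'
#' @slot nCells number of occupied voxels.
#' @slot nSurface number of surface voxels.
#' @slot centroid mean of all occupied voxel centers, voxel units.
#' @slot rs radius of the sphere with the tumor's volume, voxel units.
#' @slot chordRatio mean surface-to-centroid distance / \code{rs}.
#' @slot chordLength mean surface radial distance / maximum.
#' @slot momentOfInertia population SD of surface radial distances
#'   divided by their mean.
#' @slot circularity reciprocal of \code{momentOfInertia}.
#' @slot fractalDimension box-counting dimension of the surface.
#' @slot boxFitR2 r-squared of the log-log box-count fit.
#' @export
setClass("ShapeReport",
  representation(
    nCells = "integer",
    nSurface = "integer",
    centroid = "numeric",
    rs = "numeric",
    chordRatio = "numeric",
    chordLength = "numeric",
    momentOfInertia = "numeric",
    circularity = "numeric",
    fractalDimension = "numeric",
    boxFitR2 = "numeric"
  )
)
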