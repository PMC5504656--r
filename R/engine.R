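## Simulation engine: initialization, the daily sweep, and the run loop.
## The per-cell inner loop lives in src/engine.cpp; every stochastic draw
## there uses R's RNG, so a run is fully determined by params@seed.

.paramsList <- function(params) {
  list(
    pProlifStem = params@pProlifStem,
    pProlifProg = params@pProlifProg,
    pSymmetric = params@pSymmetric,
    pCcr5Convert = params@pCcr5Convert,
    pCcr5ConvertHypoxic = params@pCcr5ConvertHypoxic,
    divisionLimit = params@divisionLimit,
    stepsCcr5Low = params@stepsCcr5Low,
    stepsCcr5High = params@stepsCcr5High,
    maxStepsPerDay = params@maxStepsPerDay,
    hypoxiaMigrationFactor = params@hypoxiaMigrationFactor,
    hypoxiaProlifFactor = params@hypoxiaProlifFactor,
    hypoxiaOn = params@hypoxiaOn,
    maravirocOn = params@maravirocOn,
    senescentMigrate = params@senescentMigrate,
    dims = params@dims
  )
}

.emptyLog <- function() {
  data.frame(
    day = integer(), n_total = integer(), n_stem = integer(),
    n_progenitor = integer(), n_ccr5_high = integer(),
    n_quiescent = integer(), n_senescent = integer(),
    n_hypoxic = integer(), births = integer(), deaths = integer()
  )
}

.countRow <- function(sim, births, deaths) {
  cells <- sim@cells
  nHyp <- 0L
  if (sim@params@hypoxiaOn && length(sim@hypoxic) && nrow(cells)) {
    d <- sim@params@dims
    at <- cells[, 1] + d[1] * (cells[, 2] + d[2] * cells[, 3]) + 1L
    nHyp <- sum(sim@hypoxic[at])
  }
  data.frame(
    day = sim@day,
    n_total = nrow(cells),
    n_stem = sum(cells[, 4] == .LINEAGE_STEM),
    n_progenitor = sum(cells[, 4] == .LINEAGE_PROG),
    n_ccr5_high = sum(cells[, 5] == .CCR5_HIGH),
    n_quiescent = sum(cells[, 7] == .STATE_QUIESCENT),
    n_senescent = sum(cells[, 7] == .STATE_SENESCENT),
    n_hypoxic = nHyp,
    births = as.integer(births),
    deaths = as.integer(deaths)
  )
}

.seedRegion <- function(params) {
  d <- params@dims
  ax <- match(params@vesselAxis, c("x", "y", "z"))
  size <- params@seedSize
  lo <- integer(3)
  for (a in 1:3) {
    if (a == ax) {
      lo[a] <- params@vesselAnchor[a] + params@seedOffset
    } else {
      lo[a] <- (d[a] - size) %/% 2L
    }
    lo[a] <- max(0L, min(lo[a], d[a] - size))
  }
  if (any(d < size))
    stop("lattice smaller than the seeding block")
  as.matrix(expand.grid(
    i = lo[1]:(lo[1] + size - 1L),
    j = lo[2]:(lo[2] + size - 1L),
    k = lo[3]:(lo[3] + size - 1L)
  ))
}

#' Build a simulation state from an explicit cell table
#'
#' Constructs a \linkS4class{TumorSim} at day 0 from caller-supplied
#' cells, e.g. for controlled micro-experiments (measuring empirical
#' event rates) or for resuming from a snapshot. Does not touch the RNG.
#'
#' @param cells a data.frame or matrix with columns \code{i, j, k}
#'   (0-based voxel coordinates) and optionally \code{lineage}
#'   ("stem"/"progenitor" or codes 0/1), \code{ccr5} ("low"/"high" or
#'   0/1), \code{divisions}, \code{state} ("proliferative"/"quiescent"/
#'   "senescent" or codes 0/1/2). Missing columns default to
#'   proliferative CCR5-low progenitors with zero divisions.
#' @param params a \linkS4class{TumorParams}.
#' @return a \linkS4class{TumorSim} at day 0.
#' @export
simFromCells <- function(cells, params = tumorParams()) {
  cells <- as.data.frame(cells)
  n <- nrow(cells)
  dec <- function(col, levels, default) {
    if (is.null(cells[[col]])) return(rep(default, n))
    v <- cells[[col]]
    if (is.numeric(v)) return(as.integer(v))
    as.integer(match(as.character(v), levels) - 1L)
  }
  m <- cbind(
    i = as.integer(cells$i), j = as.integer(cells$j),
    k = as.integer(cells$k),
    lineage = dec("lineage", c("stem", "progenitor"), .LINEAGE_PROG),
    ccr5 = dec("ccr5", c("low", "high"), .CCR5_LOW),
    divisions = if (is.null(cells$divisions)) rep(0L, n)
                else as.integer(cells$divisions),
    state = dec("state", c("proliferative", "quiescent", "senescent"),
                .STATE_PROLIF)
  )
  storage.mode(m) <- "integer"
  hyp <- if (params@hypoxiaOn) hypoxiaField(params) else logical(0)
  sim <- new("TumorSim",
    day = 0L, cells = m, params = params, hypoxic = hyp,
    log = .emptyLog(), pendingDeaths = 0L
  )
  validObject(sim)
  sim@log <- .countRow(sim, 0L, 0L)
  sim
}

#' Initialize the tumor cell population
#'
#' Seeds the RNG from \code{params@seed}, then places the configured
#' numbers of stem/CCR5-low, stem/CCR5-high, progenitor/CCR5-high and
#' progenitor/CCR5-low cells (in that order of \code{initCounts}) on
#' distinct voxels drawn uniformly from the cubic seeding block near the
#' vessel. All cells start proliferative with zero divisions.
#'
#' @param params a \linkS4class{TumorParams}.
#' @return a \linkS4class{TumorSim} at day 0 with the day-0 record in
#'   its log.
#' @examples
#' sim <- initPopulation(tumorParams(seed = 7L))
#' nCells(sim)
#' @export
initPopulation <- function(params = tumorParams()) {
  set.seed(params@seed)
  region <- .seedRegion(params)
  n <- sum(params@initCounts)
  if (n > nrow(region))
    stop("seeding region too small: ", nrow(region), " voxels for ", n,
         " cells")
  pick <- region[sample.int(nrow(region), n), , drop = FALSE]
  cnt <- params@initCounts
  lineage <- rep(c(.LINEAGE_STEM, .LINEAGE_STEM, .LINEAGE_PROG,
                   .LINEAGE_PROG), cnt)
  ccr5 <- rep(c(.CCR5_LOW, .CCR5_HIGH, .CCR5_HIGH, .CCR5_LOW), cnt)
  simFromCells(
    data.frame(i = pick[, 1], j = pick[, 2], k = pick[, 3],
               lineage = lineage, ccr5 = ccr5),
    params
  )
}

#' Advance the simulation by one day
#'
#' Runs the daily asynchronous sweep over a uniformly shuffled snapshot
#' of the cells alive at day start. Each non-senescent cell is first
#' checked for quiescence (quiescent iff all Moore neighbors, with walls
#' counting as occupied, are filled; a free neighbor reverts quiescence);
#' non-quiescent cells then migrate their CCR5- and hypoxia-dependent
#' number of voxel steps and attempt division. Hypoxia is classified
#' from the cell's voxel at the start of its turn. Daughters born today
#' do not act today. After the sweep each senescent cell dies with
#' probability \code{pSenescentDeath}, the day is incremented and a
#' record is appended to the log.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @return the advanced \linkS4class{TumorSim}.
#' @seealso [runSimulation()]
#' @export
stepDay <- function(sim) {
  p <- sim@params
  res <- cpp_step_day(sim@cells, .paramsList(p), sim@hypoxic)
  cells <- res$cells
  ## end-of-day senescent death sweep
  deaths <- 0L
  if (nrow(cells)) {
    sen <- cells[, 7] == .STATE_SENESCENT
    if (any(sen) && p@pSenescentDeath > 0) {
      die <- sen & stats::runif(nrow(cells)) < p@pSenescentDeath
      deaths <- sum(die)
      cells <- cells[!die, , drop = FALSE]
    }
  }
  sim@cells <- cells
  sim@day <- sim@day + 1L
  rec <- .countRow(sim, res$births, deaths + sim@pendingDeaths)
  sim@pendingDeaths <- 0L
  sim@log <- rbind(sim@log, rec)
  sim
}

#' Run a simulation to completion
#'
#' Initializes the population from \code{params} and repeats [stepDay()]
#' until the day limit is reached, the population reaches
#' \code{maxCells} (checked at day end), or the population goes extinct.
#' If an anti-stem dosing schedule is configured, each dose is applied
#' at the start of its dosing day, before the daily sweep. Identical
#' \code{params} (including the seed) give bitwise-identical output.
#'
#' @param params a \linkS4class{TumorParams}.
#' @return the final \linkS4class{TumorSim}; its [timeSeries()] holds
#'   the full per-day log.
#' @examples
#' sim <- runSimulation(tumorParams(maxDays = 5L, seed = 1L))
#' timeSeries(sim)
#' @export
runSimulation <- function(params = tumorParams()) {
  sim <- initPopulation(params)
  dd <- if (is.null(params@antiStem)) integer(0)
        else doseDays(params@antiStem)
  while (sim@day < params@maxDays) {
    n <- nrow(sim@cells)
    if (n == 0L || n >= params@maxCells) break
    today <- sim@day + 1L
    if (today %in% dd)
      sim <- applyAntiStemDose(sim, params@antiStem@efficacy)
    sim <- stepDay(sim)
  }
  sim
}

#' Quiescence test for one cell
#'
#' A cell is quiescent iff every voxel of its Moore neighborhood (up to
#' 26; fewer at walls, which count as occupied) is occupied.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @param index row index of the cell in \code{sim@cells}.
#' @return logical.
#' @export
checkQuiescence <- function(sim, index) {
  cpp_check_quiescence(sim@cells, .paramsList(sim@params), as.integer(index))
}

#' Daily migration distance in voxel steps
#'
#' CCR5-low cells move \code{stepsCcr5Low} voxel steps per day and
#' CCR5-high cells \code{stepsCcr5High}; under maraviroc, CCR5-high
#' cells are inhibited to the CCR5-low speed. Hypoxia multiplies the
#' step count by \code{hypoxiaMigrationFactor} (rounded to the nearest
#' integer, minimum 1 for a positive base rate). The result is capped
#' at \code{maxStepsPerDay}.
#'
#' @param params a \linkS4class{TumorParams}.
#' @param ccr5 "low" or "high".
#' @param hypoxic logical.
#' @return integer number of voxel steps for one day.
#' @examples
#' migrationSteps(tumorParams(), "low", hypoxic = TRUE)  # 3
#' @export
migrationSteps <- function(params, ccr5 = c("low", "high"),
                           hypoxic = FALSE) {
  ccr5 <- match.arg(ccr5)
  code <- if (ccr5 == "high") .CCR5_HIGH else .CCR5_LOW
  cpp_migration_steps(.paramsList(params), code, isTRUE(hypoxic))
}

#' Convert a migration rate in micrometres per hour to voxel steps per day
#'
#' Rates from in-vitro migration assays are mapped to the lattice as
#' \code{round(rate * 24 / voxelSize)} voxel steps per day, with a
#' minimum of one step for any positive rate.
#'
#' @param umPerHour migration rate, micrometres per hour.
#' @param voxelSize voxel edge length, micrometres.
#' @return integer steps per day.
#' @examples
#' stepsFromRate(0.83)  # 1
#' stepsFromRate(5.8)   # 7
#' @export
stepsFromRate <- function(umPerHour, voxelSize = 20) {
  steps <- as.integer(round(umPerHour * 24 / voxelSize))
  ifelse(umPerHour > 0, pmax(1L, steps), 0L)
}

#' Random-walk migration of one cell
#'
#' Performs up to \code{nSteps} sequential uniform random-walk moves on
#' the lattice; each move picks uniformly among the currently free Moore
#' neighbors, and for multi-step walks the immediately previous voxel is
#' excluded as a destination. Steps with no eligible free neighbor are
#' skipped.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @param index row index of the cell to move.
#' @param nSteps number of voxel steps to attempt.
#' @return a list with the updated \code{sim} and \code{path}, an
#'   integer matrix of successive positions (starting position first).
#' @export
migrateCell <- function(sim, index, nSteps) {
  res <- cpp_migrate_cell(sim@cells, .paramsList(sim@params),
                          as.integer(index), as.integer(nSteps))
  sim@cells <- res$cells
  list(sim = sim, path = res$path)
}

#' Division attempt of one cell
#'
#' Applies the model's division rule to a single cell: a progenitor at
#' its division limit senesces; otherwise the cell divides with its
#' lineage's daily probability (halved in hypoxia) provided a free Moore
#' neighbor exists. Stem divisions are symmetric with probability
#' \code{pSymmetric}; the daughter of a symmetric division converts to
#' CCR5-high with probability \code{pCcr5Convert}
#' (\code{pCcr5ConvertHypoxic} in hypoxia), otherwise daughters inherit
#' the parent's CCR5 class. Within a compartment parent and daughter
#' share the post-division cycle count; the progenitor daughter of an
#' asymmetric stem division founds a fresh clone with a zero counter.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @param index row index of the dividing cell.
#' @param hypoxic logical; microenvironment of the cell. Default
#'   \code{NULL} classifies the cell's own voxel.
#' @param forceProb optional probability overriding the lineage division
#'   rate (e.g. 1 to force a division attempt).
#' @return a list with the updated \code{sim} and logical
#'   \code{divided}. A placed daughter is the last row of the cell
#'   table.
#' @export
attemptDivision <- function(sim, index, hypoxic = NULL, forceProb = NULL) {
  if (is.null(hypoxic)) {
    hypoxic <- FALSE
    if (sim@params@hypoxiaOn && length(sim@hypoxic)) {
      d <- sim@params@dims
      pos <- sim@cells[index, 1:3]
      hypoxic <- sim@hypoxic[pos[1] + d[1] * (pos[2] + d[2] * pos[3]) + 1L]
    }
  }
  res <- cpp_attempt_division(
    sim@cells, .paramsList(sim@params), as.integer(index),
    isTRUE(hypoxic), if (is.null(forceProb)) -1 else as.numeric(forceProb)
  )
  sim@cells <- res$cells
  list(sim = sim, divided = res$divided)
}

#' Stochastic death of senescent cells
#'
#' Removes each senescent cell independently with probability
#' \code{pSenescentDeath}; freed voxels become available immediately.
#' The removals are recorded as pending deaths and folded into the next
#' day's log record.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @return the updated \linkS4class{TumorSim}.
#' @export
applySenescentDeath <- function(sim) {
  cells <- sim@cells
  if (!nrow(cells)) return(sim)
  p <- sim@params@pSenescentDeath
  die <- cells[, 7] == .STATE_SENESCENT & stats::runif(nrow(cells)) < p
  if (any(die)) {
    sim@cells <- cells[!die, , drop = FALSE]
    sim@pendingDeaths <- sim@pendingDeaths + sum(die)
  }
  sim
}
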