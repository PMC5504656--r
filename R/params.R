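#' Construct a dosing schedule for the anti-stem-cell drug
#'
#' Defaults reproduce the reference treatment experiment: dosing starts
#' at day 150 and repeats every two weeks until day 248 (8 doses, 98
#' days of treatment).
#'
#' @param startDay first dosing day.
#' @param intervalDays days between doses.
#' @param endDay last day on which a dose may fall.
#' @param efficacy per-dose probability that each stem cell is killed.
#' @return a \linkS4class{DoseSchedule}.
#' @examples
#' doseDays(doseSchedule(efficacy = 0.75))
#' @export
doseSchedule <- function(startDay = 150L, intervalDays = 14L,
                         endDay = 248L, efficacy = 0.75) {
  new("DoseSchedule",
    startDay = as.integer(startDay),
    intervalDays = as.integer(intervalDays),
    endDay = as.integer(endDay),
    efficacy = as.numeric(efficacy)
  )
}

#' Construct the model parameter set
#'
#' Returns the full parameter set of the lattice tumor model with the
#' MDA-MB-231 reference values as defaults: 20%/day stem and 50%/day
#' progenitor division probability, 5% symmetric stem division, a
#' 12-division progenitor limit, 10%/day senescent death, migration of
#' 1 (CCR5-low) and 2 (CCR5-high) voxel steps per day, and geometric
#' hypoxia beyond 200 um of the vessel plane that halves proliferation,
#' triples migration, and raises the CCR5-high conversion probability
#' from 5% to 25%. The default initial population is 100 cells: 19
#' stem/CCR5-low, 1 stem/CCR5-high, 5 progenitor/CCR5-high and 75
#' progenitor/CCR5-low (20% stem, 6% CCR5-high), seeded uniformly on an
#' 8x8x8 voxel block near the vessel. Runs stop after 1080 days or at
#' 500,000 cells.
#'
#' @param ... named values overriding any slot of
#'   \linkS4class{TumorParams} (camelCase slot names).
#' @return a validated \linkS4class{TumorParams}.
#' @examples
#' p <- tumorParams(maxDays = 10L, seed = 42L)
#' p@pProlifStem
#' @export
tumorParams <- function(...) {
  p <- new("TumorParams",
    pProlifStem = 0.20,
    pProlifProg = 0.50,
    pSymmetric = 0.05,
    pCcr5Convert = 0.05,
    pCcr5ConvertHypoxic = 0.25,
    divisionLimit = 12L,
    pSenescentDeath = 0.10,
    stepsCcr5Low = 1L,
    stepsCcr5High = 2L,
    maxStepsPerDay = 20L,
    hypoxiaMigrationFactor = 3,
    hypoxiaProlifFactor = 0.5,
    hypoxiaDistance = 200,
    hypoxiaOn = FALSE,
    vesselKind = "plane",
    vesselAnchor = c(0L, 0L, 0L),
    vesselAxis = "x",
    maravirocOn = FALSE,
    antiStem = NULL,
    initCounts = c(19L, 1L, 5L, 75L),
    dims = c(100L, 100L, 80L),
    voxelSize = 20,
    seedOffset = 3L,
    seedSize = 8L,
    senescentMigrate = TRUE,
    maxDays = 1080L,
    maxCells = 500000L,
    seed = 1L
  )
  modifyParams(p, ...)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named slots replaced, after
#' re-validation. Integer slots are coerced from numeric input.
#'
#' @param params a \linkS4class{TumorParams}.
#' @param ... named replacement values (slot names of
#'   \linkS4class{TumorParams}).
#' @return a validated \linkS4class{TumorParams}.
#' @export
modifyParams <- function(params, ...) {
  args <- list(...)
  if (!length(args)) {
    validObject(params)
    return(params)
  }
  if (is.null(names(args)) || any(names(args) == ""))
    stop("all parameter overrides must be named")
  slots <- slotNames("TumorParams")
  intSlots <- slots[vapply(slots, function(s)
    is(slot(params, s), "integer"), logical(1))]
  for (nm in names(args)) {
    if (!nm %in% slots)
      stop("unknown parameter: ", nm)
    val <- args[[nm]]
    if (nm %in% intSlots) val <- as.integer(val)
    if (nm %in% c("pProlifStem", "pProlifProg", "pSymmetric",
                  "pCcr5Convert", "pCcr5ConvertHypoxic", "pSenescentDeath",
                  "hypoxiaMigrationFactor", "hypoxiaProlifFactor",
                  "hypoxiaDistance", "voxelSize"))
      val <- as.numeric(val)
    slot(params, nm) <- val
  }
  validObject(params)
  if (!is.null(params@antiStem)) validObject(params@antiStem)
  params
}

## Config-file key map: snake_case file keys <-> TumorParams slots.
.CONFIG_KEYS <- c(
  p_prolif_stem = "pProlifStem",
  p_prolif_prog = "pProlifProg",
  p_symmetric = "pSymmetric",
  p_ccr5_convert = "pCcr5Convert",
  p_ccr5_convert_hypoxic = "pCcr5ConvertHypoxic",
  division_limit = "divisionLimit",
  p_senescent_death = "pSenescentDeath",
  steps_ccr5_low = "stepsCcr5Low",
  steps_ccr5_high = "stepsCcr5High",
  max_steps_per_day = "maxStepsPerDay",
  hypoxia_migration_factor = "hypoxiaMigrationFactor",
  hypoxia_prolif_factor = "hypoxiaProlifFactor",
  hypoxia_distance_um = "hypoxiaDistance",
  hypoxia_on = "hypoxiaOn",
  vessel_kind = "vesselKind",
  vessel_anchor = "vesselAnchor",
  vessel_axis = "vesselAxis",
  init_counts = "initCounts",
  dims = "dims",
  voxel_size_um = "voxelSize",
  seed_offset = "seedOffset",
  seed_size = "seedSize",
  senescent_migrate = "senescentMigrate",
  max_days = "maxDays",
  max_cells = "maxCells",
  seed = "seed"
)

#' Read a run configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration into a
#' \linkS4class{TumorParams}. Keys are the snake_case spellings of the
#' parameter slots (e.g. \code{p_prolif_stem}, \code{hypoxia_on},
#' \code{hypoxia_distance_um}); interventions are nested blocks
#' \code{maraviroc: {enabled: ...}} and \code{anti_stem: {enabled,
#' start_day, interval_days, end_day, efficacy}}. Unknown keys are
#' rejected.
#'
#' @param path path to the config file.
#' @return a validated \linkS4class{TumorParams}.
#' @seealso [writeConfig()]
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of parameter keys")
  known <- c(names(.CONFIG_KEYS), "maraviroc", "anti_stem")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- list()
  for (key in intersect(names(cfg), names(.CONFIG_KEYS)))
    args[[.CONFIG_KEYS[[key]]]] <- unlist(cfg[[key]])
  p <- do.call(tumorParams, args)
  if (!is.null(cfg$maraviroc)) {
    extra <- setdiff(names(cfg$maraviroc), "enabled")
    if (length(extra))
      stop("unknown maraviroc keys: ", paste(extra, collapse = ", "))
    p <- modifyParams(p, maravirocOn = isTRUE(cfg$maraviroc$enabled))
  }
  if (!is.null(cfg$anti_stem)) {
    as_keys <- c("enabled", "start_day", "interval_days", "end_day",
                 "efficacy")
    extra <- setdiff(names(cfg$anti_stem), as_keys)
    if (length(extra))
      stop("unknown anti_stem keys: ", paste(extra, collapse = ", "))
    if (isTRUE(cfg$anti_stem$enabled)) {
      sched <- doseSchedule()
      if (!is.null(cfg$anti_stem$start_day))
        sched@startDay <- as.integer(cfg$anti_stem$start_day)
      if (!is.null(cfg$anti_stem$interval_days))
        sched@intervalDays <- as.integer(cfg$anti_stem$interval_days)
      if (!is.null(cfg$anti_stem$end_day))
        sched@endDay <- as.integer(cfg$anti_stem$end_day)
      if (!is.null(cfg$anti_stem$efficacy))
        sched@efficacy <- as.numeric(cfg$anti_stem$efficacy)
      validObject(sched)
      p <- modifyParams(p, antiStem = sched)
    }
  }
  p
}

#' Write a run configuration file
#'
#' Serializes a \linkS4class{TumorParams} to YAML in the key scheme read
#' by [readConfig()]; the round trip is lossless.
#'
#' @param params a \linkS4class{TumorParams}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(params, path) {
  cfg <- lapply(.CONFIG_KEYS, function(s) {
    v <- slot(params, s)
    if (length(v) > 1L) as.list(v) else v
  })
  names(cfg) <- names(.CONFIG_KEYS)
  cfg$maraviroc <- list(enabled = params@maravirocOn)
  if (is.null(params@antiStem)) {
    cfg$anti_stem <- list(enabled = FALSE)
  } else {
    s <- params@antiStem
    cfg$anti_stem <- list(
      enabled = TRUE, start_day = s@startDay,
      interval_days = s@intervalDays, end_day = s@endDay,
      efficacy = s@efficacy
    )
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
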