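## In-silico therapies: pulsed anti-stem-cell dosing and continuous
## CCR5 inhibition (maraviroc). Maraviroc acts inside the migration
## rule (see migrationSteps); the dosing schedule is applied by
## runSimulation at the start of each dosing day.

#' Days on which anti-stem doses are applied
#'
#' @param schedule a \linkS4class{DoseSchedule}.
#' @return integer vector: \code{startDay, startDay + intervalDays, ...}
#'   up to \code{endDay}. A schedule whose \code{endDay} precedes its
#'   \code{startDay} has no doses (empty vector).
#' @examples
#' doseDays(doseSchedule(150, 14, 248))  # 8 doses
#' @export
doseDays <- function(schedule) {
  if (schedule@startDay > schedule@endDay) return(integer(0))
  seq.int(schedule@startDay, schedule@endDay, by = schedule@intervalDays)
}

#' Apply one anti-stem-cell dose
#'
#' Kills each stem cell independently with probability \code{efficacy};
#' progenitors are untouched and freed voxels become available
#' immediately. Kills are recorded as pending deaths and folded into the
#' next day's log record.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @param efficacy per-dose kill probability for each stem cell.
#' @return the updated \linkS4class{TumorSim}.
#' @export
applyAntiStemDose <- function(sim, efficacy) {
  stopifnot(efficacy >= 0, efficacy <= 1)
  cells <- sim@cells
  if (!nrow(cells)) return(sim)
  die <- cells[, 4] == .LINEAGE_STEM & stats::runif(nrow(cells)) < efficacy
  if (any(die)) {
    sim@cells <- cells[!die, , drop = FALSE]
    sim@pendingDeaths <- sim@pendingDeaths + sum(die)
  }
  sim
}

#' Effective CCR5 class for migration under maraviroc
#'
#' Under CCR5 inhibition a CCR5-high cell migrates as if CCR5-low; the
#' receptor label itself (and CCR5 bookkeeping in the counts) is
#' unchanged. Without maraviroc the class is returned unchanged.
#'
#' @param ccr5 character vector of "low"/"high".
#' @param maravirocOn logical.
#' @return character vector of effective classes.
#' @examples
#' maravirocEffectiveClass("high", TRUE)   # "low"
#' maravirocEffectiveClass("high", FALSE)  # "high"
#' @export
maravirocEffectiveClass <- function(ccr5, maravirocOn) {
  stopifnot(all(ccr5 %in% c("low", "high")))
  if (isTRUE(maravirocOn)) rep("low", length(ccr5)) else ccr5
}
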