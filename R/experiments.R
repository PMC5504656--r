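## Experiment drivers: initial-composition helpers, replicate/sweep
## ensembles, exponential growth-curve fits, and condition comparisons.

#' Initial class quadruple from stem and CCR5-high percentages
#'
#' Rounds \code{total * stemPct / 100} stem cells and
#' \code{total * ccr5Pct / 100} CCR5-high cells, allocating the
#' CCR5-high cells between the stem and progenitor compartments
#' proportionally to their sizes (with rounding). The reference
#' composition (20, 6, 100) maps to (19, 1, 5, 75).
#'
#' @param stemPct percentage of stem cells, 0-100.
#' @param ccr5Pct percentage of CCR5-high cells, 0-100.
#' @param total total number of cells.
#' @return integer quadruple (stem/CCR5-low, stem/CCR5-high,
#'   progenitor/CCR5-high, progenitor/CCR5-low) summing to \code{total},
#'   in the order expected by \code{tumorParams(initCounts = ...)}.
#' @examples
#' compositionFromPercentages(20, 6)   # 19 1 5 75
#' @export
compositionFromPercentages <- function(stemPct, ccr5Pct, total = 100L) {
  if (stemPct < 0 || stemPct > 100 || ccr5Pct < 0 || ccr5Pct > 100)
    stop("percentages must be in [0, 100]")
  total <- as.integer(total)
  nStem <- as.integer(round(total * stemPct / 100))
  nHigh <- as.integer(round(total * ccr5Pct / 100))
  stemHigh <- as.integer(round(nHigh * nStem / total))
  stemHigh <- min(stemHigh, nStem, nHigh)
  progHigh <- min(nHigh - stemHigh, total - nStem)
  out <- c(
    nStem - stemHigh,         # stem / CCR5-low
    stemHigh,                 # stem / CCR5-high
    progHigh,                 # progenitor / CCR5-high
    total - nStem - progHigh  # progenitor / CCR5-low
  )
  stopifnot(all(out >= 0L), sum(out) == total)
  out
}

#' Fit an exponential growth law to a cell-count time series
#'
#' Ordinary least squares of \code{log(n_total)} on \code{day} over a
#' day window. The default window starts on the first day the
#' population exceeds twice its initial size and ends at the end of the
#' series or the day before the first anti-stem dose, whichever comes
#' first. For a \linkS4class{TumorSim} the start is additionally pushed
#' past the founder-cohort transient: the initial progenitors form a
#' synchronized transit-amplifying burst that exhausts its division
#' budget after about \code{divisionLimit / pProlifProg} days and decays
#' over about \code{2 / pSenescentDeath} more, so the window starts no
#' earlier than the sum of the two; the sustained (stem-driven) growth
#' phase beyond it is the regime fit by the exponential law.
#'
#' @param series a \linkS4class{TumorSim} or a time-series data.frame
#'   with columns \code{day} and \code{n_total}.
#' @param window optional integer c(first, last) day range.
#' @return a list with \code{rate} (per-day exponential constant),
#'   \code{r2}, \code{intercept} (log cells at day 0), \code{window}
#'   and \code{nDays} (points used).
#' @examples
#' df <- data.frame(day = 0:30, n_total = round(100 * exp(0.05 * 0:30)))
#' fitExponential(df)$rate
#' @export
fitExponential <- function(series, window = NULL) {
  doseStart <- NA_integer_
  transientEnd <- 0
  if (is(series, "TumorSim")) {
    p <- series@params
    if (!is.null(p@antiStem)) doseStart <- p@antiStem@startDay
    if (p@pProlifProg > 0 && p@pSenescentDeath > 0)
      transientEnd <- ceiling(p@divisionLimit / p@pProlifProg +
                                2 / p@pSenescentDeath)
    series <- timeSeries(series)
  }
  stopifnot(is.data.frame(series),
            all(c("day", "n_total") %in% names(series)))
  if (is.null(window)) {
    init <- series$n_total[1]
    above <- series$day[series$n_total > 2 * init]
    if (!length(above)) stop("population never exceeded twice its ",
                             "initial size; supply a window")
    hi <- max(series$day)
    if (!is.na(doseStart)) hi <- min(hi, doseStart - 1L)
    window <- c(max(min(above), transientEnd), hi)
  }
  sel <- series$day >= window[1] & series$day <= window[2]
  day <- series$day[sel]
  n <- series$n_total[sel]
  if (length(day) < 3L) stop("fewer than 3 days in the fit window")
  if (any(n <= 0)) stop("zero cell counts in the fit window")
  y <- log(n)
  if (stats::var(y) == 0)
    return(list(rate = 0, r2 = NA_real_, intercept = y[1],
                window = window, nDays = length(day)))
  fit <- stats::lm.fit(cbind(1, day), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(rate = unname(fit$coefficients[2]), r2 = r2,
       intercept = unname(fit$coefficients[1]), window = window,
       nDays = length(day))
}

.paramsForCondition <- function(params, setting) {
  nm <- names(setting)
  if ("stemPct" %in% nm || "ccr5Pct" %in% nm) {
    stemPct <- if ("stemPct" %in% nm) setting$stemPct else {
      cnt <- params@initCounts; 100 * (cnt[1] + cnt[2]) / sum(cnt)
    }
    ccr5Pct <- if ("ccr5Pct" %in% nm) setting$ccr5Pct else {
      cnt <- params@initCounts; 100 * (cnt[2] + cnt[3]) / sum(cnt)
    }
    params <- modifyParams(params, initCounts = compositionFromPercentages(
      stemPct, ccr5Pct, sum(params@initCounts)))
    setting <- setting[setdiff(nm, c("stemPct", "ccr5Pct"))]
  }
  if (length(setting))
    params <- do.call(modifyParams, c(list(params), setting))
  params
}

#' Run a replicate ensemble, optionally over a parameter sweep
#'
#' Runs \code{nReplicates} seeded simulations for every combination of
#' the sweep values (Cartesian product). Replicate \code{r} of condition
#' \code{c} uses seed \code{baseSeed + (c - 1) * nReplicates + (r - 1)},
#' so the whole ensemble is reproduced bit-identically from
#' \code{(params, sweep, baseSeed)}.
#'
#' @param params the base \linkS4class{TumorParams}.
#' @param nReplicates replicates per condition.
#' @param sweep named list of value vectors. Names are
#'   \linkS4class{TumorParams} slots, or the pseudo-parameters
#'   \code{stemPct} / \code{ccr5Pct} which rebalance \code{initCounts}
#'   via [compositionFromPercentages()].
#' @param baseSeed first seed of the ensemble.
#' @param snapshotDays days at which to record tumor masks (the final
#'   state is always recorded).
#' @param outputDir if non-NULL, per-run time series, per-condition
#'   mean curves, final snapshots and a summary JSON are written here.
#' @return a list with \code{series} (one data.frame; columns of the
#'   per-day log plus \code{condition}, \code{replicate}, \code{seed}
#'   and one column per sweep parameter), \code{snapshots} (nested list
#'   \code{[[condition]][[replicate]]} of \linkS4class{TumorMask}, with
#'   the final mask named \code{"final"}), \code{conditions} (data.frame
#'   of sweep settings) and \code{finalDays} (matrix of last simulated
#'   days).
#' @export
runEnsemble <- function(params = tumorParams(), nReplicates = 8L,
                        sweep = list(), baseSeed = params@seed,
                        snapshotDays = integer(0), outputDir = NULL) {
  stopifnot(nReplicates >= 1L)
  conditions <- if (length(sweep)) do.call(expand.grid, sweep)
                else data.frame(.default = 1)[, 0, drop = FALSE]
  nCond <- max(1L, nrow(conditions))
  if (!is.null(outputDir) &&
      !dir.exists(outputDir) &&
      !dir.create(outputDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outputDir)

  allSeries <- list()
  snapshots <- vector("list", nCond)
  finalDays <- matrix(NA_integer_, nCond, nReplicates)
  written <- character(0)

  condLabels <- vapply(seq_len(nCond), function(ci) {
    if (ncol(conditions))
      paste(names(conditions), unlist(conditions[ci, , drop = FALSE]),
            sep = "=", collapse = ",")
    else "default"
  }, character(1))

  for (ci in seq_len(nCond)) {
    setting <- if (ncol(conditions)) as.list(conditions[ci, , drop = FALSE])
               else list()
    condLabel <- condLabels[ci]
    p0 <- .paramsForCondition(params, setting)
    snapshots[[ci]] <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
      seed <- as.integer(baseSeed + (ci - 1L) * nReplicates + (r - 1L))
      p <- modifyParams(p0, seed = seed)
      run <- .runCapture(p, snapshotDays)
      ts <- run$sim@log
      ts$condition <- condLabel
      ts$replicate <- r
      ts$seed <- seed
      for (nm in names(setting)) ts[[nm]] <- setting[[nm]]
      allSeries[[length(allSeries) + 1L]] <- ts
      snapshots[[ci]][[r]] <- run$snapshots
      finalDays[ci, r] <- run$sim@day
      if (!is.null(outputDir)) {
        f <- file.path(outputDir, sprintf("series_c%02d_r%02d.csv", ci, r))
        utils::write.csv(ts, f, row.names = FALSE, quote = FALSE)
        written <- c(written, f)
        snapPath <- file.path(outputDir,
                              sprintf("snapshot_c%02d_r%02d_final.csv",
                                      ci, r))
        writeMaskCSV(run$snapshots$final, snapPath)
        written <- c(written, snapPath)
      }
    }
  }
  names(snapshots) <- condLabels
  series <- do.call(rbind, allSeries)

  if (!is.null(outputDir)) {
    meanCurves <- stats::aggregate(n_total ~ day + condition, series,
                                   function(v) c(mean = mean(v),
                                                 sd = stats::sd(v)))
    meanCurves <- do.call(data.frame, meanCurves)
    names(meanCurves) <- c("day", "condition", "mean_n_total",
                           "sd_n_total")
    f <- file.path(outputDir, "mean_curves.csv")
    utils::write.csv(meanCurves, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    summary <- list(
      base_seed = as.integer(baseSeed),
      n_replicates = as.integer(nReplicates),
      sweep = sweep,
      seeds = as.integer(baseSeed + seq_len(nCond * nReplicates) - 1L),
      checksums = as.list(tools::md5sum(written))
    )
    jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(series = series, snapshots = snapshots, conditions = conditions,
       finalDays = finalDays)
}

## runSimulation with mid-run mask capture (same loop and dose timing).
.runCapture <- function(params, snapshotDays = integer(0)) {
  sim <- initPopulation(params)
  dd <- if (is.null(params@antiStem)) integer(0)
        else doseDays(params@antiStem)
  snaps <- list()
  while (sim@day < params@maxDays) {
    n <- nrow(sim@cells)
    if (n == 0L || n >= params@maxCells) break
    today <- sim@day + 1L
    if (today %in% dd)
      sim <- applyAntiStemDose(sim, params@antiStem@efficacy)
    sim <- stepDay(sim)
    if (sim@day %in% snapshotDays && nrow(sim@cells))
      snaps[[paste0("day", sim@day)]] <- tumorMask(sim)
  }
  if (nrow(sim@cells)) snaps$final <- tumorMask(sim)
  list(sim = sim, snapshots = snaps)
}

#' Compare conditions at a matched day
#'
#' Summarizes replicate ensembles per condition at a given day: the
#' population size (last observation carried forward for runs that
#' stopped earlier, e.g. on reaching the cell cap) and the day each run
#' ended. Welch t-tests compare each condition against the reference
#' with the requested alternative ("less"/"greater" for directional
#' claims, "two.sided" otherwise); raw p-values are reported without
#' multiplicity correction.
#'
#' @param ensembles named list of time-series data.frames (each with
#'   columns \code{day}, \code{n_total}, \code{replicate}), e.g. splits
#'   of \code{runEnsemble()$series}.
#' @param day the comparison day.
#' @param reference name of the reference condition (default: first).
#' @param alternatives named character vector mapping condition names to
#'   t-test alternatives, interpreted as "condition is \emph{alternative}
#'   than the reference"; default "two.sided".
#' @return a list with \code{summary} (per-condition mean/sd of the
#'   day-matched population and of the final day) and \code{tests}
#'   (comparisons against the reference with p-values).
#' @export
conditionComparison <- function(ensembles, day, reference = NULL,
                                alternatives = NULL) {
  stopifnot(is.list(ensembles), length(ensembles) >= 2L,
            !is.null(names(ensembles)))
  atDay <- lapply(ensembles, function(df) {
    stopifnot(all(c("day", "n_total", "replicate") %in% names(df)))
    if (length(unique(df$replicate)) < 2L)
      stop("need at least 2 replicates per condition")
    vapply(split(df, df$replicate), function(d) {
      d <- d[order(d$day), ]
      sel <- d$day <= day
      if (!any(sel)) return(NA_real_)
      d$n_total[max(which(sel))]
    }, numeric(1))
  })
  endDay <- lapply(ensembles, function(df)
    vapply(split(df, df$replicate), function(d) max(d$day), numeric(1)))
  summary <- data.frame(
    condition = names(ensembles),
    n_replicates = lengths(atDay),
    mean_n = vapply(atDay, mean, numeric(1)),
    sd_n = vapply(atDay, stats::sd, numeric(1)),
    mean_end_day = vapply(endDay, mean, numeric(1)),
    sd_end_day = vapply(endDay, stats::sd, numeric(1)),
    row.names = NULL
  )
  if (is.null(reference)) reference <- names(ensembles)[1]
  stopifnot(reference %in% names(ensembles))
  others <- setdiff(names(ensembles), reference)
  tests <- do.call(rbind, lapply(others, function(nm) {
    alt <- if (!is.null(alternatives) && nm %in% names(alternatives))
      alternatives[[nm]] else "two.sided"
    x <- atDay[[nm]]; y <- atDay[[reference]]
    p <- if (stats::sd(c(x, y)) == 0) 1 else
      stats::t.test(x, y, alternative = alt)$p.value
    data.frame(condition = nm, reference = reference, alternative = alt,
               diff_mean = mean(x) - mean(y), p_value = p)
  }))
  list(summary = summary, tests = tests)
}
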