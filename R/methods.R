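## Accessors and show methods.

#' @rdname tnbcABM-generics
#' @aliases timeSeries,TumorSim-method
#' @export
setMethod("timeSeries", "TumorSim", function(object) object@log)

#' @rdname tnbcABM-generics
#' @aliases cellTable,TumorSim-method
#' @export
setMethod("cellTable", "TumorSim", function(object) {
  m <- object@cells
  data.frame(
    i = m[, 1], j = m[, 2], k = m[, 3],
    lineage = factor(c("stem", "progenitor")[m[, 4] + 1L],
                     levels = c("stem", "progenitor")),
    ccr5 = factor(c("low", "high")[m[, 5] + 1L],
                  levels = c("low", "high")),
    divisions = m[, 6],
    state = factor(c("proliferative", "quiescent", "senescent")[m[, 7] + 1L],
                   levels = c("proliferative", "quiescent", "senescent"))
  )
})

#' @rdname tnbcABM-generics
#' @aliases nCells,TumorSim-method
#' @export
setMethod("nCells", "TumorSim", function(object) nrow(object@cells))

#' @rdname tnbcABM-generics
#' @aliases nCells,TumorMask-method
#' @export
setMethod("nCells", "TumorMask", function(object) nrow(object@coords))

#' @rdname tnbcABM-generics
#' @aliases simDay,TumorSim-method
#' @export
setMethod("simDay", "TumorSim", function(object) object@day)

setMethod("show", "TumorParams", function(object) {
  cat("TumorParams\n")
  cat(sprintf("  lattice: %d x %d x %d voxels (%g um each)\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@voxelSize))
  cat(sprintf("  division/day: stem %.2f (symmetric %.2f), progenitor %.2f (limit %d)\n",
              object@pProlifStem, object@pSymmetric, object@pProlifProg,
              object@divisionLimit))
  cat(sprintf("  migration steps/day: CCR5-low %d, CCR5-high %d (cap %d)\n",
              object@stepsCcr5Low, object@stepsCcr5High,
              object@maxStepsPerDay))
  cat(sprintf("  senescent death/day: %.2f\n", object@pSenescentDeath))
  cat(sprintf("  hypoxia: %s (> %g um; prolif x%g, migration x%g, conversion %.2f -> %.2f)\n",
              if (object@hypoxiaOn) "on" else "off",
              object@hypoxiaDistance, object@hypoxiaProlifFactor,
              object@hypoxiaMigrationFactor, object@pCcr5Convert,
              object@pCcr5ConvertHypoxic))
  cat(sprintf("  maraviroc: %s; anti-stem: %s\n",
              if (object@maravirocOn) "on" else "off",
              if (is.null(object@antiStem)) "none"
              else sprintf("days %d..%d every %d (efficacy %.2f)",
                           object@antiStem@startDay, object@antiStem@endDay,
                           object@antiStem@intervalDays,
                           object@antiStem@efficacy)))
  cat(sprintf("  init: %s (stem-low, stem-high, prog-high, prog-low); stop: %d days or %d cells; seed %d\n",
              paste(object@initCounts, collapse = "/"), object@maxDays,
              object@maxCells, object@seed))
  invisible(object)
})

setMethod("show", "DoseSchedule", function(object) {
  dd <- doseDays(object)
  cat(sprintf("DoseSchedule: day %d to %d every %d days (%d doses), efficacy %.2f\n",
              object@startDay, object@endDay, object@intervalDays,
              length(dd), object@efficacy))
  invisible(object)
})

setMethod("show", "TumorSim", function(object) {
  m <- object@cells
  cat(sprintf("TumorSim: day %d, %d cells (%d stem, %d progenitor; %d CCR5-high; %d quiescent, %d senescent)\n",
              object@day, nrow(m), sum(m[, 4] == .LINEAGE_STEM),
              sum(m[, 4] == .LINEAGE_PROG), sum(m[, 5] == .CCR5_HIGH),
              sum(m[, 7] == .STATE_QUIESCENT),
              sum(m[, 7] == .STATE_SENESCENT)))
  invisible(object)
})

setMethod("show", "TumorMask", function(object) {
  cat(sprintf("TumorMask: %d voxels on a %d x %d x %d lattice\n",
              nrow(object@coords), object@dims[1], object@dims[2],
              object@dims[3]))
  invisible(object)
})

setMethod("show", "ShapeReport", function(object) {
  cat("ShapeReport\n")
  cat(sprintf("  cells: %d (surface %d), r_s = %.2f voxels\n",
              object@nCells, object@nSurface, object@rs))
  cat(sprintf("  chord ratio %.3f | chord length %.3f | moment of inertia %.3f\n",
              object@chordRatio, object@chordLength,
              object@momentOfInertia))
  cat(sprintf("  circularity %.3f | fractal dimension %.3f (fit r2 %.3f)\n",
              object@circularity, object@fractalDimension,
              object@boxFitR2))
  invisible(object)
})

#' Coerce a shape report to a one-row data.frame
#'
#' @param x a \linkS4class{ShapeReport}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a one-row data.frame with all metric fields.
#' @export
as.data.frame.ShapeReport <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(
    n_cells = x@nCells, n_surface = x@nSurface,
    centroid_i = x@centroid[1], centroid_j = x@centroid[2],
    centroid_k = x@centroid[3], r_s = x@rs,
    chord_ratio = x@chordRatio, chord_length = x@chordLength,
    moment_of_inertia = x@momentOfInertia, circularity = x@circularity,
    fractal_dimension = x@fractalDimension, box_fit_r2 = x@boxFitR2
  )
}

#' Write shape reports as CSV
#'
#' @param reports a \linkS4class{ShapeReport}, a list of them, or the
#'   per-component data.frame from [shapeReport()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeShapeReport <- function(reports, path) {
  df <- if (is.data.frame(reports)) reports
  else if (is(reports, "ShapeReport")) as.data.frame(reports)
  else do.call(rbind, lapply(reports, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
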