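#' @name tnbcABM-generics
#' @title Accessor generics
#' @description Accessors for the simulation and morphometry classes.
#' @param object a \linkS4class{TumorSim}, \linkS4class{TumorMask} or
#'   \linkS4class{ShapeReport}.
#' @keywords internal
NULL

#' @describeIn tnbcABM-generics per-day time series of a simulation.
#' @export
setGeneric("timeSeries", function(object) standardGeneric("timeSeries"))

#' @describeIn tnbcABM-generics cell table as a labelled data.frame.
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))

#' @describeIn tnbcABM-generics number of live cells / occupied voxels.
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @describeIn tnbcABM-generics current simulated day.
#' @export
setGeneric("simDay", function(object) standardGeneric("simDay"))

#' Build a tumor voxel mask
#'
#' Extracts the set of occupied voxels of a tumor snapshot as a
#' \linkS4class{TumorMask}, the input to all shape metrics.
#'
#' @param object a \linkS4class{TumorSim}, an integer matrix of 0-based
#'   voxel coordinates, or a data.frame with columns \code{i, j, k}.
#' @param ... passed to the methods.
#' @return a \linkS4class{TumorMask}.
#' @examples
#' mask <- tumorMask(cbind(0:3, 0L, 0L))
#' nCells(mask)
#' @export
setGeneric("tumorMask", function(object, ...) standardGeneric("tumorMask"))
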