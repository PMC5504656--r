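## Plain-text input/output: time-series CSV, snapshot CSV, bare voxel
## masks (CSV/JSON) and a legacy-ASCII VTK point cloud.

#' Write the per-day time series as CSV
#'
#' Column order: day, n_total, n_stem, n_progenitor, n_ccr5_high,
#' n_quiescent, n_senescent, n_hypoxic, births, deaths, plus
#' \code{replicate} and \code{seed}.
#'
#' @param sim a \linkS4class{TumorSim} (or a time-series data.frame).
#' @param path output CSV path.
#' @param replicate,seed identifying columns added to every row;
#'   \code{seed} defaults to the run's seed.
#' @return \code{path}, invisibly.
#' @export
writeTimeSeries <- function(sim, path, replicate = 1L, seed = NULL) {
  ts <- if (is(sim, "TumorSim")) timeSeries(sim) else sim
  if (is.null(seed))
    seed <- if (is(sim, "TumorSim")) sim@params@seed else NA_integer_
  ts$replicate <- as.integer(replicate)
  ts$seed <- as.integer(seed)
  utils::write.csv(ts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cell snapshot as CSV
#'
#' One row per cell with columns \code{x_um, y_um, z_um} (voxel centers
#' in micrometres), \code{i, j, k} (0-based voxel indices),
#' \code{lineage, ccr5, state} (labels) and \code{divisions}.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @seealso [readSnapshot()], [writeVTK()]
#' @export
writeSnapshot <- function(sim, path) {
  ct <- cellTable(sim)
  vs <- sim@params@voxelSize
  out <- data.frame(
    x_um = (ct$i + 0.5) * vs, y_um = (ct$j + 0.5) * vs,
    z_um = (ct$k + 0.5) * vs,
    i = ct$i, j = ct$j, k = ct$k,
    lineage = ct$lineage, ccr5 = ct$ccr5, state = ct$state,
    divisions = ct$divisions
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell snapshot CSV
#'
#' @param path a CSV written by [writeSnapshot()].
#' @return a data.frame; pass to [tumorMask()] for shape metrics or to
#'   [simFromCells()] to resume simulating.
#' @export
readSnapshot <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a bare voxel mask as CSV
#'
#' @param mask a \linkS4class{TumorMask}.
#' @param path output path; one row per voxel, columns \code{i,j,k}.
#' @return \code{path}, invisibly.
#' @export
writeMaskCSV <- function(mask, path) {
  utils::write.csv(as.data.frame(mask@coords), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a voxel mask from CSV or JSON
#'
#' Accepts the engine snapshot format (columns \code{i,j,k} among
#' others), a bare \code{i,j,k} CSV, or a JSON array of [i, j, k]
#' triples (or an object with fields \code{i}, \code{j}, \code{k}).
#'
#' @param path input file; format chosen by extension (.json vs CSV).
#' @param ... passed to [tumorMask()] (e.g. \code{dims}).
#' @return a \linkS4class{TumorMask}.
#' @export
readMask <- function(path, ...) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- if (is.matrix(x)) x else as.matrix(as.data.frame(x))
    colnames(m) <- c("i", "j", "k")
    return(tumorMask(m, ...))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j", "k") %in% names(df)))
  tumorMask(df, ...)
}

#' Write a snapshot as a legacy-ASCII VTK point cloud
#'
#' Points are voxel centers in micrometres with integer point scalars
#' \code{lineage} (0 stem, 1 progenitor), \code{ccr5} (0 low, 1 high)
#' and \code{state} (0 proliferative, 1 quiescent, 2 senescent), for
#' viewing in ParaView or similar.
#'
#' @param sim a \linkS4class{TumorSim}.
#' @param path output .vtk path.
#' @return \code{path}, invisibly.
#' @export
writeVTK <- function(sim, path) {
  cells <- sim@cells
  n <- nrow(cells)
  vs <- sim@params@voxelSize
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "tumor cell point cloud",
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d float", n)
  ), con)
  pts <- (cells[, 1:3, drop = FALSE] + 0.5) * vs
  utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POINT_DATA %d", n), con)
  fields <- c(lineage = 4L, ccr5 = 5L, state = 7L)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s int 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(cells[, fields[[nm]]]), con)
  }
  invisible(path)
}
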