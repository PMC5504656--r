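## Geometric hypoxia: a static vessel structure (a plane or a line) and
## the per-voxel distance map derived from it. A voxel is hypoxic iff
## its distance to the vessel strictly exceeds the threshold (200 um by
## default). There is no oxygen transport model; the field is purely
## geometric and precomputed once per run.

#' Describe the vessel geometry
#'
#' @param kind "plane" (default: the well-oxygenated normal-tissue face)
#'   or "line" (a single vessel running along one axis).
#' @param anchor integer voxel triple the geometry passes through.
#' @param axis for a plane, the axis perpendicular to it; for a line,
#'   the axis it runs along.
#' @return a list describing the geometry, used by [distanceToVessel()]
#'   and [hypoxiaField()].
#' @export
vesselGeometry <- function(kind = c("plane", "line"),
                           anchor = c(0L, 0L, 0L), axis = "x") {
  kind <- match.arg(kind)
  if (!axis %in% c("x", "y", "z")) stop("axis must be 'x', 'y' or 'z'")
  list(kind = kind, anchor = as.integer(anchor), axis = axis)
}

.vesselFromParams <- function(params) {
  vesselGeometry(params@vesselKind, params@vesselAnchor, params@vesselAxis)
}

#' Distance from voxels to the vessel structure
#'
#' Euclidean distance, in micrometres, from each voxel center to the
#' nearest point of the vessel: perpendicular distance for a plane,
#' point-to-line distance for a line. Distances are measured between
#' voxel centers, so a voxel in the anchor layer is at distance 0.
#'
#' @param voxels integer matrix (n x 3) or length-3 vector of 0-based
#'   voxel coordinates.
#' @param geometry a [vesselGeometry()] list.
#' @param voxelSize voxel edge length in micrometres.
#' @return numeric vector of distances in micrometres.
#' @examples
#' distanceToVessel(c(11, 40, 20), vesselGeometry("plane"))  # 220
#' @export
distanceToVessel <- function(voxels, geometry, voxelSize = 20) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  ax <- match(geometry$axis, c("x", "y", "z"))
  delta <- sweep(voxels, 2, geometry$anchor)
  if (geometry$kind == "plane") {
    d <- abs(delta[, ax])
  } else {
    perp <- setdiff(1:3, ax)
    d <- sqrt(delta[, perp[1]]^2 + delta[, perp[2]]^2)
  }
  d * voxelSize
}

#' Precompute the per-voxel hypoxia field
#'
#' @param params a \linkS4class{TumorParams}.
#' @return logical vector of length \code{prod(dims)} in column-major
#'   voxel order (x fastest), \code{TRUE} where the distance to the
#'   vessel strictly exceeds \code{hypoxiaDistance}.
#' @seealso [isHypoxic()], [writeHypoxiaMask()]
#' @export
hypoxiaField <- function(params) {
  d <- params@dims
  vox <- as.matrix(expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L),
                               k = 0:(d[3] - 1L)))
  dist <- distanceToVessel(vox, .vesselFromParams(params), params@voxelSize)
  dist > params@hypoxiaDistance
}

#' Hypoxia classification of voxels
#'
#' @param voxels integer matrix (n x 3) or length-3 vector of 0-based
#'   voxel coordinates.
#' @param params a \linkS4class{TumorParams}. When \code{hypoxiaOn} is
#'   \code{FALSE} every voxel is normoxic.
#' @return logical vector.
#' @examples
#' isHypoxic(c(11, 0, 0), tumorParams(hypoxiaOn = TRUE))  # TRUE (220 um)
#' isHypoxic(c(10, 0, 0), tumorParams(hypoxiaOn = TRUE))  # FALSE (200 um)
#' @export
isHypoxic <- function(voxels, params) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  if (!params@hypoxiaOn) return(rep(FALSE, nrow(voxels)))
  dist <- distanceToVessel(voxels, .vesselFromParams(params),
                           params@voxelSize)
  dist > params@hypoxiaDistance
}

#' Hypoxia-adjusted rate modifiers
#'
#' @param hypoxic logical, as returned by [isHypoxic()] (always
#'   \code{FALSE} when hypoxia is globally disabled).
#' @param params a \linkS4class{TumorParams}.
#' @return a list with \code{prolif} (multiplier on division
#'   probability), \code{migration} (multiplier on voxel steps per day)
#'   and \code{ccr5Conversion} (per symmetric division probability of a
#'   CCR5-high daughter). Under defaults: (1, 1, 0.05) normoxic and
#'   (0.5, 3, 0.25) hypoxic.
#' @export
hypoxiaModifiers <- function(hypoxic, params = tumorParams()) {
  if (isTRUE(hypoxic)) {
    list(prolif = params@hypoxiaProlifFactor,
         migration = params@hypoxiaMigrationFactor,
         ccr5Conversion = params@pCcr5ConvertHypoxic)
  } else {
    list(prolif = 1, migration = 1, ccr5Conversion = params@pCcr5Convert)
  }
}

#' Export the hypoxia mask as CSV
#'
#' Writes one row per voxel with columns \code{i,j,k,hypoxic} for
#' debugging or plotting.
#'
#' @param params a \linkS4class{TumorParams}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeHypoxiaMask <- function(params, path) {
  d <- params@dims
  vox <- expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L),
                     k = 0:(d[3] - 1L))
  vox$hypoxic <- as.integer(hypoxiaField(params))
  utils::write.csv(vox, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
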