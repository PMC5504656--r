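## 3D tumor shape metrics. All five metrics are dimensionless ratios of
## distances measured in voxel lengths, computed from the radial profile
## of the tumor surface: the Euclidean distances d_c from each surface
## voxel center to the centroid of ALL occupied voxel centers.
##   chord ratio       mean(d_c) / r_s,  r_s = (3 n / 4 pi)^(1/3)
##   chord length      mean(d_c) / max(d_c)
##   moment of inertia population SD of d_c / mean(d_c)
##   circularity       1 / moment of inertia
##   fractal dimension box-counting slope on the surface voxel set
## Larger chord ratio / moment of inertia and smaller chord length mean
## a more finger-like (invasive) morphology.

.MOORE <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(g == 0L) < 3L, , drop = FALSE]
})

#' @describeIn tumorMask mask of all live cells of a simulation
#'   snapshot (walls are the simulation lattice).
#' @export
setMethod("tumorMask", "TumorSim", function(object, ...) {
  new("TumorMask",
    coords = object@cells[, 1:3, drop = FALSE],
    dims = object@params@dims,
    voxelSize = object@params@voxelSize
  )
})

#' @describeIn tumorMask mask from an integer matrix (n x 3) of 0-based
#'   occupied voxel coordinates.
#' @param dims lattice extent; defaults to the bounding box plus a
#'   one-voxel free margin, so a standalone mask behaves like a tumor in
#'   a larger grid.
#' @param voxelSize voxel edge length, micrometres.
#' @export
setMethod("tumorMask", "matrix", function(object, dims = NULL,
                                          voxelSize = 20, ...) {
  m <- object
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("i", "j", "k"))
  if (is.null(dims)) dims <- apply(m, 2, max) + 2L
  new("TumorMask", coords = m, dims = as.integer(dims),
      voxelSize = as.numeric(voxelSize))
})

#' @describeIn tumorMask mask from a data.frame with columns
#'   \code{i, j, k} (e.g. a snapshot read by [readSnapshot()]).
#' @export
setMethod("tumorMask", "data.frame", function(object, dims = NULL,
                                              voxelSize = 20, ...) {
  stopifnot(all(c("i", "j", "k") %in% names(object)))
  tumorMask(as.matrix(object[, c("i", "j", "k")]), dims = dims,
            voxelSize = voxelSize)
})

.voxelKey <- function(coords, d) {
  (coords[, 3] * d[2] + coords[, 2]) * d[1] + coords[, 1]
}

#' Surface (periphery) voxels of a tumor mask
#'
#' The periphery is the tumor's outer boundary: the occupied voxels
#' with at least one Moore neighbor belonging to the exterior-connected
#' free space, found by a 6-connected flood fill of free voxels from
#' the lattice boundary. Interior cavities (e.g. vacancies left by
#' senescent cell death inside the tumor bulk) are not periphery.
#' Out-of-bounds voxels count as occupied (static walls), matching the
#' simulation engine, so a mask that fills its lattice has no surface.
#'
#' @param mask a \linkS4class{TumorMask}.
#' @return integer matrix (n x 3) of surface voxel coordinates.
#' @examples
#' nrow(extractSurface(generateFixture("ball", radius = 5)))
#' @export
extractSurface <- function(mask) {
  surf <- cpp_exterior_surface(mask@coords, mask@dims)
  mask@coords[surf, , drop = FALSE]
}

#' Radial profile of a tumor mask
#'
#' @param mask a \linkS4class{TumorMask}.
#' @return a list with \code{centroid} (arithmetic mean of all occupied
#'   voxel centers, voxel units), \code{distances} (Euclidean distances
#'   from each surface voxel center to the centroid, voxel lengths) and
#'   \code{surface} (the surface coordinates).
#' @export
radialProfile <- function(mask) {
  surf <- extractSurface(mask)
  centroid <- unname(colMeans(mask@coords))
  delta <- sweep(surf, 2, centroid)
  list(centroid = centroid, distances = sqrt(rowSums(delta^2)),
       surface = surf)
}

.sphereRadius <- function(n) (3 * n / (4 * pi))^(1 / 3)

#' Chord ratio
#'
#' Mean surface-to-centroid distance divided by the radius of the
#' sphere with the tumor's volume (occupied voxel count). Near 1 for a
#' compact ball; larger for finger-like morphologies.
#'
#' @param mask a \linkS4class{TumorMask}.
#' @return numeric.
#' @export
chordRatio <- function(mask) {
  prof <- radialProfile(mask)
  mean(prof$distances) / .sphereRadius(nrow(mask@coords))
}

#' Chord length
#'
#' Mean surface radial distance divided by the maximum. Near 1 for a
#' ball; smaller for finger-like morphologies. \code{NA} for a
#' single-voxel mask (zero maximum distance).
#'
#' @param mask a \linkS4class{TumorMask}.
#' @return numeric.
#' @export
chordLength <- function(mask) {
  d <- radialProfile(mask)$distances
  mx <- max(d)
  if (mx == 0) return(NA_real_)
  mean(d) / mx
}

#' Moment of inertia (normalized radial spread)
#'
#' Population standard deviation of the surface radial distances divided
#' by their mean. Zero for a perfect spherical shell; larger for
#' finger-like morphologies. \code{NA} when the mean radial distance is
#' zero.
#'
#' @param mask a \linkS4class{TumorMask}.
#' @return numeric.
#' @export
momentOfInertia <- function(mask) {
  d <- radialProfile(mask)$distances
  mu <- mean(d)
  if (mu == 0) return(NA_real_)
  sqrt(mean((d - mu)^2)) / mu
}

#' Circularity
#'
#' Mean surface radial distance divided by its population standard
#' deviation: the exact reciprocal of [momentOfInertia()]. Returns
#' \code{Inf} for a zero-variance profile (perfect compactness) and
#' \code{NA} when undefined (zero mean).
#'
#' @param mask a \linkS4class{TumorMask}.
#' @return numeric.
#' @export
circularity <- function(mask) {
  moi <- momentOfInertia(mask)
  if (is.na(moi)) return(NA_real_)
  if (moi == 0) return(Inf)
  1 / moi
}

#' Box-counting fractal dimension of the tumor surface
#'
#' Counts the boxes of side length 2, 4, 8, 16 and 32 voxels (grid
#' anchored at the surface's bounding-box corner) that contain at least
#' one surface voxel, and fits log N(s) against log(1/s) by ordinary
#' least squares. The slope is the dimension estimate; the fit's
#' r-squared is returned alongside. Note the estimate is scale-window
#' dependent: for masks whose extent is comparable to the largest box
#' sizes, coarse boxes see the enclosed volume and pull the slope above
#' the fine-scale surface dimension.
#'
#' @param mask a \linkS4class{TumorMask}.
#' @param sizes box side lengths in voxels.
#' @return a list with \code{dimension}, \code{r2} and the count table
#'   \code{counts} (data.frame with \code{size}, \code{n}).
#' @export
fractalDimension <- function(mask, sizes = c(2L, 4L, 8L, 16L, 32L)) {
  surf <- extractSurface(mask)
  lo <- apply(surf, 2, min)
  rel <- sweep(surf, 2, lo)
  n <- vapply(sizes, function(s) {
    box <- rel %/% s
    nrow(unique(box))
  }, numeric(1))
  keep <- n > 0
  if (sum(keep) < 2L)
    stop("degenerate scale range: fewer than 2 usable box sizes")
  x <- log(1 / sizes[keep])
  y <- log(n[keep])
  if (stats::var(y) == 0) {
    return(list(dimension = 0, r2 = NA_real_,
                counts = data.frame(size = sizes, n = n)))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(dimension = unname(fit$coefficients[2]), r2 = r2,
       counts = data.frame(size = sizes, n = n))
}

#' Compute all shape metrics of one snapshot
#'
#' @param mask a \linkS4class{TumorMask}.
#' @param perComponent if \code{TRUE}, metrics are computed separately
#'   for each 26-connected component (for disconnected "self-metastasis"
#'   morphologies) and a data.frame is returned; by default one report
#'   over the union of all occupied voxels with a single global
#'   centroid.
#' @return a \linkS4class{ShapeReport}, or a data.frame of per-component
#'   metrics when \code{perComponent = TRUE}.
#' @examples
#' shapeReport(generateFixture("ball", radius = 8))
#' @export
shapeReport <- function(mask, perComponent = FALSE) {
  if (perComponent) {
    comps <- connectedComponents(mask)
    out <- do.call(rbind, lapply(comps, function(cm)
      as.data.frame(shapeReport(cm))))
    out$component <- seq_along(comps)
    return(out)
  }
  prof <- radialProfile(mask)
  d <- prof$distances
  mu <- mean(d)
  mx <- max(d)
  sdev <- sqrt(mean((d - mu)^2))
  moi <- if (mu == 0) NA_real_ else sdev / mu
  fd <- tryCatch(fractalDimension(mask),
                 error = function(e) list(dimension = NA_real_,
                                          r2 = NA_real_))
  new("ShapeReport",
    nCells = nrow(mask@coords),
    nSurface = nrow(prof$surface),
    centroid = unname(prof$centroid),
    rs = .sphereRadius(nrow(mask@coords)),
    chordRatio = mu / .sphereRadius(nrow(mask@coords)),
    chordLength = if (mx == 0) NA_real_ else mu / mx,
    momentOfInertia = moi,
    circularity = if (is.na(moi)) NA_real_
                  else if (moi == 0) Inf else 1 / moi,
    fractalDimension = fd$dimension,
    boxFitR2 = fd$r2
  )
}

#' Split a mask into 26-connected components
#'
#' @param mask a \linkS4class{TumorMask}.
#' @return a list of \linkS4class{TumorMask} objects, largest first.
#' @export
connectedComponents <- function(mask) {
  coords <- mask@coords
  n <- nrow(coords)
  d <- mask@dims
  key <- .voxelKey(coords, d)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  half <- .MOORE[seq_len(13), , drop = FALSE]  # one of each +/- pair
  for (r in seq_len(nrow(half))) {
    off <- half[r, ]
    nb <- cbind(coords[, 1] + off[1], coords[, 2] + off[2],
                coords[, 3] + off[3])
    nbKey <- (nb[, 3] * d[2] + nb[, 2]) * d[1] + nb[, 1]
    hit <- match(nbKey, key)
    ok <- which(!is.na(hit))
    for (a in ok) {
      ra <- find(a); rb <- find(hit[a])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  groups <- groups[order(-lengths(groups))]
  lapply(groups, function(rows)
    new("TumorMask", coords = coords[rows, , drop = FALSE], dims = d,
        voxelSize = mask@voxelSize))
}
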