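## Deterministic digitized reference shapes for the shape-metric
## oracle tests and the CLI `fixture` command.

#' Generate a deterministic voxelized reference shape
#'
#' Digitized analytic shapes used to validate the shape metrics:
#' \describe{
#'   \item{ball}{voxels whose center lies within \code{radius} (voxel
#'     lengths, Euclidean) of the center voxel.}
#'   \item{rod}{a 1 x 1 x \code{length} line of voxels along z.}
#'   \item{ellipsoid}{voxels with
#'     \code{(x/a)^2 + (y/b)^2 + (z/c)^2 <= 1} for semi-axes
#'     \code{axes = c(a, b, c)}.}
#'   \item{cube_shell}{the one-voxel-thick shell of a filled cube of
#'     edge \code{length}.}
#'   \item{two_clusters}{the union of two balls of radius \code{radius}
#'     whose centers are \code{separation} voxels apart along x
#'     (emulating disconnected "self-metastasis" morphologies).}
#' }
#'
#' @param shape one of "ball", "rod", "ellipsoid", "cube_shell",
#'   "two_clusters".
#' @param radius ball radius in voxel lengths.
#' @param length rod or cube edge length in voxels.
#' @param axes semi-axes of the ellipsoid, voxel lengths.
#' @param separation center separation of the two clusters, voxels.
#' @param voxelSize voxel edge length in micrometres.
#' @return a \linkS4class{TumorMask}.
#' @examples
#' nCells(generateFixture("ball", radius = 10))  # 4169
#' @export
generateFixture <- function(shape = c("ball", "rod", "ellipsoid",
                                      "cube_shell", "two_clusters"),
                            radius = 10, length = 64,
                            axes = c(16, 8, 8), separation = 2 * radius + 4,
                            voxelSize = 20) {
  shape <- match.arg(shape)
  ballCoords <- function(r, center) {
    r0 <- ceiling(r)
    g <- as.matrix(expand.grid(x = -r0:r0, y = -r0:r0, z = -r0:r0))
    g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
    sweep(g, 2, center, "+")
  }
  coords <- switch(shape,
    ball = {
      c0 <- rep(ceiling(radius) + 1, 3)
      ballCoords(radius, c0)
    },
    rod = cbind(1L, 1L, seq_len(length)),
    ellipsoid = {
      a <- ceiling(axes)
      g <- as.matrix(expand.grid(x = -a[1]:a[1], y = -a[2]:a[2],
                                 z = -a[3]:a[3]))
      g <- g[(g[, 1] / axes[1])^2 + (g[, 2] / axes[2])^2 +
               (g[, 3] / axes[3])^2 <= 1, , drop = FALSE]
      sweep(g, 2, a + 1, "+")
    },
    cube_shell = {
      g <- as.matrix(expand.grid(x = seq_len(length), y = seq_len(length),
                                 z = seq_len(length)))
      onFace <- g[, 1] %in% c(1, length) | g[, 2] %in% c(1, length) |
        g[, 3] %in% c(1, length)
      g[onFace, , drop = FALSE]
    },
    two_clusters = {
      c0 <- rep(ceiling(radius) + 1, 3)
      c1 <- c0 + c(round(separation), 0, 0)
      u <- rbind(ballCoords(radius, c0), ballCoords(radius, c1))
      u[!duplicated(u), , drop = FALSE]
    }
  )
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("i", "j", "k")
  tumorMask(coords, voxelSize = voxelSize)
}
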