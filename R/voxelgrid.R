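#' Construct a VoxelGrid
#'
#' @param voxels 3D array, x-fastest.
#' @param spacing voxel spacing mm (scalar or length 3).
#' @param origin world mm of the centre of voxel `[1,1,1]`.
#' @return a [VoxelGrid-class].
#' @examples
#' g <- voxelGrid(array(0, c(4, 4, 4)), spacing = 1, origin = c(0, 0, 0))
#' dim(g)
#' @export
voxelGrid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  new("VoxelGrid", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' World coordinates of the voxel centres along each axis
#' @param grid a [VoxelGrid-class].
#' @return list of numeric vectors (x, y, z).
#' @export
gridAxes <- function(grid) {
  d <- dim(grid@voxels)
  lapply(1:3, function(a) grid@origin[a] + (seq_len(d[a]) - 1) * grid@spacing[a])
}

# 0-based continuous index of world points (n x 3 matrix)
.worldToIndex <- function(grid, pts) {
  sweep(sweep(pts, 2, grid@origin), 2, grid@spacing, "/")
}

#' Trilinear interpolation of a grid at world points
#'
#' Samples the grid at arbitrary mm positions; values are linear between the
#' 8 surrounding voxel centres. Points outside the sampled region (beyond the
#' outermost voxel centres) return `outside`.
#'
#' @param grid a [VoxelGrid-class].
#' @param pts n x 3 matrix of world mm points.
#' @param outside value for points outside the grid (default 0).
#' @param nearest if `TRUE`, nearest-neighbour lookup instead of trilinear
#'   (used for label grids).
#' @return numeric vector of sampled values.
#' @export
sampleGrid <- function(grid, pts, outside = 0, nearest = FALSE) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- dim(grid@voxels)
  ix <- .worldToIndex(grid, pts)
  out <- rep(as.numeric(outside), nrow(pts))
  if (nearest) {
    i <- round(ix) + 1
    ok <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
      i[, 3] >= 1 & i[, 3] <= d[3]
    lin <- (i[ok, 1]) + d[1] * (i[ok, 2] - 1) + d[1] * d[2] * (i[ok, 3] - 1)
    out[ok] <- grid@voxels[lin]
    return(out)
  }
  ok <- ix[, 1] >= 0 & ix[, 1] <= d[1] - 1 & ix[, 2] >= 0 &
    ix[, 2] <= d[2] - 1 & ix[, 3] >= 0 & ix[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  p <- ix[ok, , drop = FALSE]
  i0 <- pmin(floor(p), rep(d, each = nrow(p)) - 2)
  i0 <- pmax(i0, 0)
  f <- p - i0
  v <- grid@voxels
  lin <- function(dx, dy, dz) {
    v[(i0[, 1] + dx + 1) + d[1] * (i0[, 2] + dy) + d[1] * d[2] * (i0[, 3] + dz)]
  }
  val <-
    lin(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    lin(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    lin(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    lin(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    lin(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    lin(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    lin(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    lin(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[ok] <- val
  out
}

#' Resample a grid onto a new regular geometry
#'
#' Trilinear resampling (nearest-neighbour for label-style grids) onto the
#' geometry given by `spacing`, covering the same physical extent.
#'
#' @param grid a [VoxelGrid-class].
#' @param spacing target spacing mm (scalar or length 3).
#' @param nearest nearest-neighbour instead of trilinear.
#' @return a [VoxelGrid-class] on the new geometry.
#' @export
resampleGrid <- function(grid, spacing, nearest = FALSE) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  d <- dim(grid@voxels)
  ext <- (d - 1) * grid@spacing
  nd <- pmax(2L, as.integer(floor(ext / spacing)) + 1L)
  ax <- lapply(1:3, function(a) grid@origin[a] + (seq_len(nd[a]) - 1) * spacing[a])
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- sampleGrid(grid, pts, outside = grid@voxels[1], nearest = nearest)
  voxelGrid(array(vals, nd), spacing = spacing, origin = grid@origin)
}
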