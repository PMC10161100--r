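#' Identity rigid transform
#' @return a [RigidTransform-class].
#' @export
identityTransform <- function() {
  new("RigidTransform", rotation = diag(3), translation = c(0, 0, 0))
}

#' Build a rigid transform from an axis-angle rotation and translation
#' @param angleDeg rotation angle, degrees.
#' @param axis rotation axis (default z).
#' @param translation length-3 mm vector.
#' @param center rotation centre, mm.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(angleDeg = 0, axis = c(0, 0, 1),
                           translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  a <- angleDeg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  t <- as.numeric(center - R %*% center + translation)
  new("RigidTransform", rotation = R, translation = t)
}

#' Apply / invert / compose rigid transforms
#' @param t,a,b [RigidTransform-class] objects.
#' @param pts n x 3 matrix (or length-3 vector) of mm points.
#' @return transformed points; a [RigidTransform-class] for invert/compose.
#' @export
applyTransform <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(t@rotation), 2, t@translation, "+")
}

#' @rdname applyTransform
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% t@translation))
}

#' @rdname applyTransform
#' @export
composeTransforms <- function(a, b) {  # a after b
  new("RigidTransform", rotation = a@rotation %*% b@rotation,
      translation = as.numeric(a@rotation %*% b@translation +
                                 a@translation))
}

#' Detect metal-pin centroids in a CT grid
#'
#' Thresholds the CT, labels connected components (6-connectivity) and
#' returns the intensity-weighted centroid of each, ordered canonically by
#' angle about their common centroid (in the plane of largest spread).
#'
#' @param ct [VoxelGrid-class] of HU.
#' @param threshold HU threshold for metal (default 2000).
#' @return 3 x 3 matrix of centroids, mm.
#' @export
detectPinCentroidsCT <- function(ct, threshold = 2000) {
  mask <- ct@voxels > threshold
  lab <- cpp_label_components(as.integer(mask), dim(ct@voxels))
  k <- attr(lab, "n")
  if (k != 3L)
    stop("expected 3 metal components above threshold, found ", k)
  d <- dim(ct@voxels)
  idx <- which(lab > 0)
  w <- as.vector(ct@voxels)[idx] - threshold
  co <- arrayInd(idx, d)
  pos <- sweep(sweep(co - 1, 2, ct@spacing, "*"), 2, ct@origin, "+")
  cen <- t(vapply(1:3, function(g) {
    s <- lab[idx] == g
    colSums(pos[s, , drop = FALSE] * w[s]) / sum(w[s])
  }, numeric(3)))
  .orderByAngle(cen)
}

#' Detect fiducial hole centroids in a film image
#'
#' Finds zero-dose connected components (4-connectivity) and returns the
#' unweighted geometric centroid of each hole's pixel set in film-frame mm,
#' ordered canonically by angle about their common centroid.
#'
#' @param film a [FilmImage-class].
#' @param tol dose below which a pixel counts as a hole.
#' @return 3 x 2 matrix of film-frame centroids, mm.
#' @export
detectHoleCentroidsFilm <- function(film, tol = 1e-9) {
  mask <- film@pixels <= tol
  lab <- cpp_label_components(as.integer(mask), dim(film@pixels))
  k <- attr(lab, "n")
  if (k != 3L) stop("expected 3 film holes, found ", k)
  d <- dim(film@pixels)
  idx <- which(lab > 0)
  co <- arrayInd(idx, d)
  uv <- sweep((co - 1) * film@pitch, 2, film@offset, "+")
  cen <- t(vapply(1:3, function(g) {
    s <- lab[idx] == g
    colMeans(uv[s, , drop = FALSE])
  }, numeric(2)))
  ctr <- colMeans(cen)
  cen[order(atan2(cen[, 2] - ctr[2], cen[, 1] - ctr[1])), ]
}

# order 3D points by angle about their centroid in the plane of largest
# spread (principal plane)
.orderByAngle <- function(pts) {
  ctr <- colMeans(pts)
  c0 <- sweep(pts, 2, ctr)
  sv <- svd(c0)
  uv <- c0 %*% sv$v[, 1:2]
  pts[order(atan2(uv[, 2], uv[, 1])), , drop = FALSE]
}

#' Least-squares rigid fit of point correspondences
#'
#' Closed-form rotation + translation (no scale, no reflection) minimising
#' the RMS correspondence distance, via the cross-covariance SVD with a
#' proper-rotation (determinant +1) constraint. With three points the fit
#' is exact for congruent triangles. For three points all six pairings of
#' the canonically ordered sets are tried and the lowest-RMS one kept.
#'
#' @param fixed,moving n x 3 matrices of corresponding points (n >= 3);
#'   the returned transform maps `moving` onto `fixed`.
#' @param tryCyclic try the cyclic correspondence shifts (default TRUE for
#'   n = 3).
#' @return a [RigidTransform-class] with an `rms` attribute (mm).
#' @export
fitRigid <- function(fixed, moving, tryCyclic = nrow(fixed) == 3L) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  stopifnot(nrow(fixed) == nrow(moving), ncol(fixed) == 3)
  .area <- function(p) {
    if (nrow(p) != 3) return(Inf)
    sqrt(sum(.cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])^2)) / 2
  }
  if (nrow(fixed) == 3 && (.area(fixed) < 1e-6 || .area(moving) < 1e-6))
    stop("fiducial points are collinear; rigid fit is degenerate")
  fit1 <- function(mv) {
    cf <- colMeans(fixed); cm <- colMeans(mv)
    H <- crossprod(sweep(mv, 2, cm), sweep(fixed, 2, cf))
    sv <- svd(H)
    s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% s %*% t(sv$u)
    tr <- as.numeric(cf - R %*% cm)
    rms <- sqrt(mean(rowSums((sweep(mv %*% t(R), 2, tr, "+") - fixed)^2)))
    list(R = R, t = tr, rms = rms)
  }
  perms <- if (tryCyclic)
    list(1:3, c(2, 3, 1), c(3, 1, 2), c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  else list(seq_len(nrow(moving)))
  best <- NULL
  for (p in perms) {
    f <- fit1(moving[p, , drop = FALSE])
    if (is.null(best) || f$rms < best$rms) best <- f
  }
  out <- new("RigidTransform", rotation = best$R, translation = best$t)
  attr(out, "rms") <- best$rms
  out
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Resample a 3D dose grid onto a film raster
#'
#' Trilinear interpolation of the dose grid at the transformed film pixel
#' centres: pixel (u, v) samples the grid at
#' `t(frameOrigin + u ex + v ey)`.
#'
#' @param dose a [DoseGrid-class].
#' @param t a [RigidTransform-class] (film frame -> grid frame).
#' @param raster a [FilmImage-class] providing the target raster, or a
#'   list with pitch, offset, dims, frameOrigin, ex, ey.
#' @return a [FilmImage-class] carrying the resampled dose and the dose
#'   grid's reporting-medium flag.
#' @export
resampleDoseToFilm <- function(dose, t, raster) {
  if (is(raster, "FilmImage")) {
    spec <- list(pitch = raster@pitch, offset = raster@offset,
                 dims = dim(raster@pixels), frameOrigin = raster@frameOrigin,
                 ex = raster@ex, ey = raster@ey)
  } else spec <- raster
  u <- spec$offset[1] + (seq_len(spec$dims[1]) - 1) * spec$pitch
  v <- spec$offset[2] + (seq_len(spec$dims[2]) - 1) * spec$pitch
  uv <- as.matrix(expand.grid(u = u, v = v))
  world <- matrix(spec$frameOrigin, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %o% spec$ex + uv[, 2] %o% spec$ey
  world <- applyTransform(t, world)
  ix <- .worldToIndex(dose, world)
  d <- dim(dose@voxels)
  inside <- ix[, 1] >= 0 & ix[, 1] <= d[1] - 1 & ix[, 2] >= 0 &
    ix[, 2] <= d[2] - 1 & ix[, 3] >= 0 & ix[, 3] <= d[3] - 1
  if (!any(inside)) stop("transformed raster lies fully outside the grid")
  px <- matrix(sampleGrid(dose, world), spec$dims[1], spec$dims[2])
  new("FilmImage", pixels = px, pitch = spec$pitch, offset = spec$offset,
      frameOrigin = spec$frameOrigin, ex = spec$ex, ey = spec$ey,
      medium = dose@medium, holes = matrix(numeric(0), 0, 2))
}

#' Write / read a rigid transform as JSON
#' @param t a [RigidTransform-class].
#' @param path file path.
#' @export
writeTransformJson <- function(t, path) {
  jsonlite::write_json(list(rotation = t@rotation,
                            translation = t@translation),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTransformJson
#' @export
readTransformJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- if (is.matrix(j$rotation)) j$rotation else
    matrix(unlist(j$rotation), 3, 3, byrow = TRUE)
  new("RigidTransform", rotation = R,
      translation = as.numeric(j$translation))
}
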