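test_that("rigid fit recovers known transforms exactly on noiseless data", {
  pins <- phantomSpec()@pins
  tt <- rigidTransform(30, c(0, 0, 1), c(5, -3, 2), center = c(100, 100, 100))
  fit <- fitRigid(fixed = applyTransform(tt, pins), moving = pins)
  expect_lt(attr(fit, "rms"), 1e-9)
  expect_lt(max(abs(fit@rotation - tt@rotation)), 1e-9)
  expect_lt(max(abs(fit@translation - tt@translation)), 1e-9)
  # identity on identical sets
  fid <- fitRigid(pins, pins)
  expect_lt(max(abs(fid@rotation - diag(3))), 1e-12)
  expect_lt(max(abs(fid@translation)), 1e-12)
})

test_that("rotation determinant is +1 for arbitrary noisy correspondences", {
  set.seed(12)
  pins <- phantomSpec()@pins
  for (i in 1:20) {
    f <- fitRigid(pins + matrix(rnorm(9, 0, 2), 3, 3), pins)
    expect_equal(det(f@rotation), 1, tolerance = 1e-9)
  }
})

test_that("collinear fiducials are rejected", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(fitRigid(a, a), "collinear")
})

test_that("fiducial jitter displaces film points within the expected scale", {
  set.seed(13)
  pins <- phantomSpec()@pins
  gp <- cbind(as.matrix(expand.grid(x = seq(60, 140, 10),
                                    y = seq(60, 140, 10))), 100)
  disp <- replicate(200, {
    f <- fitRigid(fixed = pins + matrix(rnorm(9, 0, 0.5), 3, 3),
                  moving = pins)
    mean(sqrt(rowSums((applyTransform(f, gp) - gp)^2)))
  })
  expect_lt(quantile(disp, 0.95), 1.5)
})

test_that("pin centroids are recovered from the synthetic CT", {
  spec <- phantomSpec(spacing = c(0.53, 0.53, 1))
  lab <- buildPhantom(spec)
  mats <- materialTable()
  ct <- synthesizeCT(lab, mats, defaultCurve(), noiseSd = 0)
  cen <- detectPinCentroidsCT(ct)
  nearestErr <- function(found) max(apply(found, 1, function(p)
    min(sqrt(rowSums(sweep(spec@pins, 2, p)^2)))))
  expect_lt(nearestErr(cen), 0.5 * max(spacing(lab)) * sqrt(3))
  # noisy CT: still within 0.5 mm
  ctN <- synthesizeCT(lab, mats, defaultCurve(), noiseSd = 20, seed = 2)
  expect_lt(nearestErr(detectPinCentroidsCT(ctN)), 0.5)
  # wrong component count is reported
  expect_error(detectPinCentroidsCT(ct, threshold = 1e6), "found 0")
})

test_that("hole centroids sit at the lance positions, radius-invariant", {
  dose <- new("DoseGrid",
              voxels = array(5, c(41, 41, 21)), spacing = c(1, 1, 1),
              origin = c(80, 80, 90), medium = "medium",
              uncertainty = NULL)
  pins <- rbind(c(95, 100, 100), c(100, 107, 100), c(107, 96, 100))
  uv <- pins[, 1:2] - 100
  filmA <- simulateFilm(dose, filmPlane(), sizeMm = c(30, 30), pins = pins,
                        holeRadius = 0.3)
  filmB <- simulateFilm(dose, filmPlane(), sizeMm = c(30, 30), pins = pins,
                        holeRadius = 0.7)
  cenA <- detectHoleCentroidsFilm(filmA)
  cenB <- detectHoleCentroidsFilm(filmB)
  nearestErr <- function(found) max(apply(found, 1, function(p)
    min(sqrt(rowSums(sweep(uv, 2, p)^2)))))
  expect_lt(nearestErr(cenA), 0.5 * filmA@pitch)
  expect_lt(max(abs(cenA - cenB)), 0.1)
  noHoles <- simulateFilm(dose, filmPlane(), sizeMm = c(30, 30))
  expect_error(detectHoleCentroidsFilm(noHoles), "found 0")
})

test_that("dose resampling onto a film raster matches the grid slices", {
  set.seed(14)
  v <- array(runif(30 * 30 * 10, 1, 5), c(30, 30, 10))
  dose <- new("DoseGrid", voxels = v, spacing = c(1, 1, 1),
              origin = c(86, 86, 96), medium = "medium", uncertainty = NULL)
  raster <- list(pitch = 1, offset = c(-10, -10), dims = c(21L, 21L),
                 frameOrigin = c(100, 100, 100), ex = c(1, 0, 0),
                 ey = c(0, 1, 0))
  # identity: equals the z = 100 slice at voxel centres
  f <- resampleDoseToFilm(dose, identityTransform(), raster)
  expect_equal(f@pixels, v[5:25, 5:25, 5], tolerance = 1e-12)
  # translation by one voxel pitch: equals the neighbouring slice
  tz <- rigidTransform(translation = c(0, 0, 1))
  f2 <- resampleDoseToFilm(dose, tz, raster)
  expect_equal(f2@pixels, v[5:25, 5:25, 6], tolerance = 1e-12)
  # fully outside -> error
  tout <- rigidTransform(translation = c(1000, 0, 0))
  expect_error(resampleDoseToFilm(dose, tout, raster), "outside")
})

test_that("resampling through a transform and back is the identity", {
  v <- array(0, c(41, 41, 21))
  ax <- seq_len(41) - 21; az <- seq_len(21) - 11
  v <- outer(outer(exp(-(ax / 12)^2), exp(-(ax / 12)^2)),
             exp(-(az / 8)^2)) * 5 + 1
  dose <- new("DoseGrid", voxels = v, spacing = c(1, 1, 1),
              origin = c(80, 80, 90), medium = "medium", uncertainty = NULL)
  raster <- list(pitch = 0.5, offset = c(-8, -8), dims = c(33L, 33L),
                 frameOrigin = c(100, 100, 100), ex = c(1, 0, 0),
                 ey = c(0, 1, 0))
  tt <- rigidTransform(10, c(0, 0, 1), c(1, 0.5, 0), center = c(100, 100, 100))
  fwd <- resampleDoseToFilm(dose, tt, raster)
  back <- resampleDoseToFilm(dose, composeTransforms(invertTransform(tt), tt),
                             raster)
  ident <- resampleDoseToFilm(dose, identityTransform(), raster)
  expect_equal(back@pixels, ident@pixels, tolerance = 1e-12)
})
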