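test_that("radiological depth integrates density exactly on uniform media", {
  g <- voxelGrid(array(1, c(20, 20, 20)), spacing = 10, origin = c(5, 5, 5))
  # 10 cm chord of water
  expect_equal(radiologicalDepth(g, c(0, 50, 50), c(100, 50, 50)), 10,
               tolerance = 1e-9)
  # half water + half bone: 5 cm each
  v <- array(1, c(20, 20, 20)); v[11:20, , ] <- 1.72
  g2 <- voxelGrid(v, spacing = 10, origin = c(5, 5, 5))
  expect_equal(radiologicalDepth(g2, c(50, 50, 50), c(150, 50, 50)),
               5 + 5 * 1.72, tolerance = 1e-9)
  # zero-length and non-intersecting segments
  expect_equal(radiologicalDepth(g, c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(radiologicalDepth(g, c(-50, -50, -50), c(-60, -50, -50)), 0)
})

test_that("radiological depth matches a midpoint-quadrature oracle", {
  set.seed(21)
  for (i in 1:5) {
    v <- array(runif(12 * 13 * 14, 0.2, 2), c(12, 13, 14))
    g <- voxelGrid(v, spacing = c(2, 1.5, 3), origin = c(0, 0, 0))
    p0 <- runif(3, -10, 5)
    p1 <- runif(3, c(20, 16, 36), c(30, 25, 50))
    # midpoint quadrature with nearest-voxel lookup, 1e4 steps
    tt <- (seq_len(1e4) - 0.5) / 1e4
    pts <- outer(tt, p1 - p0) + matrix(p0, 1e4, 3, byrow = TRUE)
    vals <- sampleGrid(g, pts, outside = 0, nearest = TRUE)
    L <- sqrt(sum((p1 - p0)^2))
    oracle <- sum(vals) * L / 1e4 * 0.1
    expect_equal(radiologicalDepth(g, p0, p1), oracle, tolerance = 1e-3)
  }
})

test_that("beam primary follows attenuation, inverse square and penumbra", {
  mach <- defaultMachine()
  water <- voxelGrid(array(1, c(50, 50, 50)), spacing = 4,
                     origin = c(2, 2, 2))
  src <- c(100, 100, 500)
  focus <- c(100, 100, 100)
  onAxis <- beamDose(focus, src, 16, water, mach)
  # on-axis value: OF16 * exp(-mu * d_rad) at unit inverse-square
  drad <- radiologicalDepth(water, src, focus)
  expect_equal(onAxis, 1 * exp(-0.063 * drad), tolerance = 1e-3)
  # far off-axis: < 1% of on-axis
  offAxis <- beamDose(c(140, 100, 100), src, 16, water, mach)
  expect_lt(offAxis, 0.01 * onAxis)
  # a bone slab on the ray lowers primary by exp(-mu * thickness * 0.72)
  vb <- voxels(water)
  zsel <- which(abs(gridAxes(water)[[3]] - 150) <= 15)
  vb[, , zsel] <- 1.72
  bone <- voxelGrid(vb, spacing = 4, origin = c(2, 2, 2))
  slab_cm <- length(zsel) * spacing(water)[3] / 10  # voxelized thickness
  ratio <- beamDose(focus, src, 16, bone, mach) / onAxis
  expect_equal(ratio, exp(-0.063 * slab_cm * 0.72), tolerance = 1e-3)
})

test_that("primary dose is monotone non-increasing with added depth", {
  mach <- defaultMachine()
  water <- voxelGrid(array(1, c(50, 50, 50)), spacing = 4,
                     origin = c(2, 2, 2))
  src <- c(100, 100, 500)
  depths <- seq(120, 180, by = 4)
  d <- vapply(depths, function(z)
    beamDose(c(100, 100, 200 - z + 100), src, 16, water, mach), numeric(1))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("calibration closure holds on a coarse water sphere", {
  plan <- singleShotPlan()
  maps <- coarseWaterMaps()
  gs <- coarseGridSpec(plan)
  dose <- computePlanDose(plan, maps, gridSpec = gs, traceSpacing = 2)
  cal <- attr(dose, "calibration")
  ucp <- sampleGrid(dose, matrix(c(100, 100, 100), 1))
  expect_equal(ucp, plan@refRate * cal$bot, tolerance = 1e-3)
  expect_equal(max(voxels(dose)), 8)  # 4 Gy at 50% isodose
  expect_equal(reportingMedium(dose), "medium")
  expect_equal(cal$F, plan@refRate / cal$refRel * cal$bot)
})

test_that("the 50% isodose surface of the reference shot is near-spherical", {
  plan <- singleShotPlan()
  dose <- computePlanDose(plan, coarseWaterMaps(),
                          gridSpec = coarseGridSpec(plan), traceSpacing = 2)
  ax <- gridAxes(dose)
  iso <- function(dirn) {
    pts <- matrix(c(100, 100, 100), 41, 3, byrow = TRUE) +
      outer(seq(0, 20, 0.5), dirn)
    v <- sampleGrid(dose, pts)
    approx(v, seq(0, 20, 0.5), xout = 4)$y  # radius where dose = 4 Gy
  }
  radii <- c(iso(c(1, 0, 0)), iso(c(0, 1, 0)), iso(c(-1, 0, 0)),
             iso(c(0, -1, 0)))
  expect_lt((max(radii) - min(radii)) / mean(radii), 0.15)
})

test_that("dose is invariant under 90-degree rotations in a uniform sphere", {
  plan <- singleShotPlan()
  dose <- computePlanDose(plan, coarseWaterMaps(),
                          gridSpec = coarseGridSpec(plan), traceSpacing = 2)
  for (r in c(2, 4, 6, 8)) {
    v <- sampleGrid(dose, rbind(c(100 + r, 100, 100), c(100, 100 + r, 100),
                                c(100 - r, 100, 100), c(100, 100 - r, 100)))
    expect_lt((max(v) - min(v)) / mean(v), 0.005)
  }
})

test_that("air gap on the beam path raises the downstream dose", {
  # slab phantom: water everywhere vs water with a 15 mm air gap
  mk <- function(withAir) {
    v <- array(1, c(40, 40, 60))
    if (withAir) v[, , 25:39] <- 0.0012  # 15 mm air at 1 mm spacing
    voxelGrid(v, spacing = 1, origin = c(81, 81, 61))
  }
  mach <- defaultMachine()
  src <- c(100, 100, 500)
  p <- c(100, 100, 70)  # downstream of the gap
  dAir <- beamDose(p, src, 16, mk(TRUE), mach)
  dWat <- beamDose(p, src, 16, mk(FALSE), mach)
  expect_gt(dAir, dWat)
  expect_equal(dAir / dWat, exp(0.063 * (1 - 0.0012) * 1.5),
               tolerance = 0.02)
})

test_that("empty plans and invalid grids are rejected", {
  expect_error(new("Plan", shots = list(), prescriptionDose = 4,
                   prescriptionIsodose = 50, refRate = 3.215,
                   refDate = as.Date("2022-01-01")), "at least one shot")
})
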