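test_that("default machine geometry: 192 sources aimed at the focus", {
  m <- defaultMachine()
  expect_equal(nrow(m@sources), 192L)
  expect_equal(as.vector(table(m@sources$sector)), rep(24L, 8))
  pos <- as.matrix(m@sources[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(pos, 2, m@focus)^2))
  expect_lt(max(abs(d - m@sfd)), 1e-9)
  # unit directions toward the focus by construction
  dir <- sweep(-sweep(pos, 2, m@focus), 1, d, "/")
  expect_lt(max(abs(sqrt(rowSums(dir^2)) - 1)), 1e-12)
})

test_that("sector azimuthal spans are disjoint 45-degree wedges", {
  m <- defaultMachine()
  phi <- atan2(m@sources$y - 100, m@sources$x - 100) * 180 / pi
  phi <- (phi + 360) %% 360
  for (sec in 1:8) {
    p <- phi[m@sources$sector == sec]
    expect_true(all(p >= (sec - 1) * 45 - 1e-9 & p < sec * 45 + 1e-9))
    expect_length(p, 24L)
  }
})

test_that("decay correction follows the cobalt-60 half-life", {
  d0 <- as.Date("2021-01-01")
  expect_equal(decayCorrectedRate(3.215, d0, d0), 3.215)
  halfLife <- d0 + round(CO60_HALF_LIFE_Y * 365.25)
  expect_equal(decayCorrectedRate(3.215, d0, halfLife), 3.215 / 2,
               tolerance = 1e-4)
  # one year: direct exponential evaluation oracle
  expect_equal(decayCorrectedRate(3.215, d0, d0 + 365),
               3.215 * 2^(-(365 / 365.25) / CO60_HALF_LIFE_Y))
  expect_equal(3.215 * 2^(-1 / CO60_HALF_LIFE_Y), 2.818847,
               tolerance = 1e-6)
  expect_error(decayCorrectedRate(3.215, d0, d0 - 1), "precedes")
})

test_that("decay correction is multiplicative over consecutive intervals", {
  d0 <- as.Date("2020-03-01")
  d1 <- d0 + 211
  d2 <- d1 + 1000
  direct <- decayCorrectedRate(3.215, d0, d2)
  chained <- decayCorrectedRate(decayCorrectedRate(3.215, d0, d1), d1, d2)
  expect_equal(direct, chained, tolerance = 1e-12)
})

test_that("chamber dose is the product chain and linear in charge", {
  m <- new("ChamberMeasurement", M = 1, kTP = 1, kPol = 1, kIon = 1,
           NDw = 1, kQ = 1, kQmsr = 1)
  expect_equal(chamberDose(m), 1)
  # default msr correction is applied
  mDef <- new("ChamberMeasurement", M = 1, NDw = 1)
  expect_equal(chamberDose(mDef), 1.0037)
  set.seed(5)
  for (i in 1:10) {
    v <- runif(7, 0.5, 2)
    mm <- new("ChamberMeasurement", M = v[1], kTP = v[2], kPol = v[3],
              kIon = v[4], NDw = v[5], kQ = v[6], kQmsr = v[7])
    expect_equal(chamberDose(mm), prod(v), tolerance = 1e-12)
    m2 <- mm; m2@M <- 2 * mm@M
    expect_equal(chamberDose(m2), 2 * chamberDose(mm), tolerance = 1e-12)
  }
})

test_that("sector sampling probabilities follow t N / sum(t N)", {
  # two active categories with times 1 and 2, equal phase-space counts
  s1 <- shot(sectors = c("16", rep("blocked", 7)), weight = 1)
  s2 <- shot(sectors = c("16", rep("blocked", 7)), weight = 2)
  plan <- new("Plan", shots = list(s1, s2), prescriptionDose = 4,
              prescriptionIsodose = 50, refRate = 3.215,
              refDate = as.Date("2022-01-01"))
  sp <- sectorProbabilities(plan)
  expect_equal(sp@table$p, c(1 / 3, 2 / 3))
  # equal t, unequal phase-space counts 100 vs 300
  s3 <- shot(sectors = c("4", "8", rep("blocked", 6)))
  plan2 <- new("Plan", shots = list(s3), prescriptionDose = 4,
               prescriptionIsodose = 50, refRate = 3.215,
               refDate = as.Date("2022-01-01"))
  sp2 <- sectorProbabilities(plan2, phspCounts = c("4" = 100, "8" = 300,
                                                   "16" = 1))
  expect_equal(sp2@table$p, c(0.25, 0.75))
  # equal everything over n_s sectors
  sp3 <- sectorProbabilities(singleShotPlan())
  expect_equal(sp3@table$p, rep(1 / 8, 8))
  expect_equal(sum(sp3@table$p), 1, tolerance = 1e-12)
  # all-blocked null shot -> error
  null <- shot(sectors = rep("blocked", 8), weight = 0)
  plan3 <- new("Plan", shots = list(null), prescriptionDose = 4,
               prescriptionIsodose = 50, refRate = 3.215,
               refDate = as.Date("2022-01-01"))
  expect_error(sectorProbabilities(plan3), "zero")
})

test_that("prescription normalization scales the maximum and the BOT", {
  rel <- voxelGrid(array(runif(125, 0, 2), c(5, 5, 5)), spacing = 1,
                   origin = c(0, 0, 0))
  plan <- singleShotPlan(prescriptionDose = 4, prescriptionIsodose = 50)
  n <- normalizePrescription(rel, plan, refRel = 1)
  expect_equal(n$scale * max(voxels(rel)), 8)  # 4 Gy at 50% -> max 8 Gy
  plan100 <- singleShotPlan(prescriptionDose = 4, prescriptionIsodose = 100)
  n100 <- normalizePrescription(rel, plan100, refRel = 1)
  expect_equal(n100$scale * max(voxels(rel)), 4)
  # doubling the reference rate halves BOT, scale unchanged
  plan2 <- singleShotPlan(refRate = 2 * 3.215)
  n2 <- normalizePrescription(rel, plan2, refRel = 1)
  expect_equal(n2$bot, n$bot / 2, tolerance = 1e-12)
  expect_equal(n2$scale, n$scale)
  expect_error(normalizePrescription(
    voxelGrid(array(0, c(2, 2, 2)), 1, c(0, 0, 0)), plan, 1),
    "positive maximum")
})
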