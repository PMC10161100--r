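# fast MC settings: coarse water sphere, small dose grid around the UCP
.mcSetup <- function() {
  plan <- singleShotPlan()
  dose <- computePlanDose(plan, coarseWaterMaps(),
                          gridSpec = coarseGridSpec(plan), traceSpacing = 2)
  plan@bot <- attr(dose, "calibration")$bot
  list(plan = plan, det = dose)
}

test_that("MC-lite is bit-reproducible under a fixed seed", {
  s <- .mcSetup()
  a <- mcLiteDose(s$plan, coarseWaterMaps(), nHistories = 5e3,
                  nBatches = 5, seed = 42, traceSpacing = 2,
                  gridSpec = coarseGridSpec(s$plan))
  b <- mcLiteDose(s$plan, coarseWaterMaps(), nHistories = 5e3,
                  nBatches = 5, seed = 42, traceSpacing = 2,
                  gridSpec = coarseGridSpec(s$plan))
  expect_identical(voxels(a), voxels(b))
  expect_identical(a@uncertainty, b@uncertainty)
})

test_that("MC-lite carries batch uncertainties and a positive dose field", {
  s <- .mcSetup()
  mc <- mcLiteDose(s$plan, coarseWaterMaps(), nHistories = 2e4,
                   nBatches = 10, seed = 1, traceSpacing = 2,
                   gridSpec = coarseGridSpec(s$plan))
  expect_false(is.null(mc@uncertainty))
  expect_equal(reportingMedium(mc), "medium")
  ucp <- sampleGrid(mc, matrix(c(100, 100, 100), 1))
  expect_gt(ucp, 0)
})

test_that("sampled sector frequencies match the sampling distribution", {
  # two active categories with phase-space counts 100 and 300 -> P = .25/.75
  sh <- shot(sectors = c("4", "8", rep("blocked", 6)))
  plan <- new("Plan", shots = list(sh), prescriptionDose = 4,
              prescriptionIsodose = 50, refRate = 3.215,
              refDate = as.Date("2022-01-01"), bot = 1)
  counts <- c("4" = 100, "8" = 300, "16" = 1)
  sp <- sectorProbabilities(plan, counts)
  expect_equal(sp@table$p, c(0.25, 0.75))
  mc <- mcLiteDose(plan, coarseWaterMaps(), nHistories = 1e5,
                   nBatches = 5, seed = 3, traceSpacing = 2,
                   gridSpec = coarseGridSpec(plan), phspCounts = counts,
                   refPerHistory = list(value = 1, se = 0))
  obs <- attr(mc, "mc")$counts
  expect_equal(sum(obs), 1e5)
  # within 3 sd of binomial
  expect_lt(abs(obs[1] - 0.25e5), 3 * sqrt(1e5 * 0.25 * 0.75))
  chi <- suppressWarnings(chisq.test(obs, p = sp@table$p))
  expect_gt(chi$p.value, 0.01)
})

test_that("batch uncertainty scales as one over the square root of histories", {
  s <- .mcSetup()
  sizes <- c(1e4, 4e4, 16e4)
  relU <- vapply(sizes, function(n) {
    mc <- mcLiteDose(s$plan, coarseWaterMaps(), nHistories = n,
                     nBatches = 8, seed = 9, traceSpacing = 2,
                     gridSpec = coarseGridSpec(s$plan),
                     refPerHistory = list(value = 1, se = 0))
    hi <- voxels(mc) > 0.5 * max(voxels(mc))
    mean(mc@uncertainty[hi])
  }, numeric(1))
  slope <- coef(lm(log(relU) ~ log(sizes)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("MC-lite agrees with the deterministic engine at the UCP", {
  s <- .mcSetup()
  mc <- mcLiteDose(s$plan, coarseWaterMaps(), nHistories = 1e5,
                   nBatches = 10, seed = 5, traceSpacing = 2,
                   gridSpec = coarseGridSpec(s$plan))
  ucpMc <- sampleGrid(mc, matrix(c(100, 100, 100), 1))
  ucpDet <- s$plan@refRate * s$plan@bot
  info <- attr(mc, "mc")
  seTot <- sqrt(info$ucpSe^2 +
                  (ucpDet * info$refPerHistory$se / info$refPerHistory$value)^2)
  expect_lt(abs(ucpMc - ucpDet), 3 * seTot)
})

test_that("MC-lite validates its inputs", {
  s <- .mcSetup()
  expect_error(mcLiteDose(s$plan, coarseWaterMaps(), nHistories = 5,
                          nBatches = 10), "nHistories >= nBatches")
  planNoBot <- singleShotPlan()
  expect_error(mcLiteDose(planNoBot, coarseWaterMaps(), nHistories = 100,
                          nBatches = 2), "beam-on time")
})
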