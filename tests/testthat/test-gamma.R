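test_that("resampling preserves linear ramps and native-pitch identity", {
  prof <- seq(2, 6, length.out = 21)   # linear ramp, pitch 1
  r <- resampleMap(prof, 0.1)
  ex <- r$org + (seq_along(r$values) - 1) * 0.1
  expect_equal(r$values, 2 + (6 - 2) / 20 * ex, tolerance = 1e-12)
  rSame <- resampleMap(prof, 1)
  expect_equal(rSame$values, prof, tolerance = 1e-12)
  m <- matrix(runif(64, 1, 2), 8, 8)
  r2 <- resampleMap(m, 1)
  expect_equal(r2$values, m, tolerance = 1e-12)
  expect_error(resampleMap(prof, 100), "extent")
})

test_that("optimized gamma equals the exhaustive oracle on random 2D maps", {
  set.seed(30)
  crit <- gammaCriteria(searchRadius = Inf)
  for (i in 1:5) {
    A <- matrix(2 + runif(100), 10, 10)
    B <- A * (1 + 0.02 * matrix(rnorm(100), 10, 10))
    res <- gammaMap(A, B, crit)
    expect_equal(gammaValues(res), bruteGamma2d(A, B), tolerance = 1e-9)
  }
})

test_that("gamma worked examples: self, uniform offset, small shift", {
  A <- matrix(4, 12, 12)
  self <- gammaMap(A, A, gammaCriteria())
  expect_true(all(gammaValues(self)[self@mask] == 0))
  expect_equal(passRate(self), 100)
  # uniform maps, evaluated = 1.06 x reference: dose term only, gamma = 2
  off <- gammaMap(A, A * 1.06, gammaCriteria())
  expect_equal(max(abs(gammaValues(off)[off@mask] - 2)), 0, tolerance = 1e-9)
  expect_equal(passRate(off), 0)
  # translation by 0.5 mm with a gradient: gamma <= 0.5 + resample tolerance
  x <- seq(0, 19, by = 1)
  ramp <- outer(2 + 0.2 * x, rep(1, 20))
  shifted <- outer(2 + 0.2 * (x - 0.5), rep(1, 20))
  tr <- gammaMap(ramp, shifted, gammaCriteria())
  inner <- gammaValues(tr)[3:18, ]
  expect_lt(max(inner, na.rm = TRUE), 0.5 + 0.05)
  expect_equal(passRate(tr), 100)
})

test_that("1D gamma matches its oracle and the DTA boundary case", {
  set.seed(31)
  prof <- 3 + cumsum(rnorm(40, 0, 0.05))
  evalp <- prof * (1 + 0.01 * rnorm(40))
  crit <- gammaCriteria(searchRadius = Inf)
  expect_equal(gammaProfile1d(prof, evalp, crit),
               bruteGamma1d(prof, evalp), tolerance = 1e-9)
  expect_true(all(gammaProfile1d(prof, prof, crit)[prof > 1] == 0))
  # steep ramp shifted by exactly the DTA: gamma ~ 1 at the boundary
  x <- seq(0, 30, by = 1)
  r <- 2 + 0.5 * x
  s <- 2 + 0.5 * (x - 1)
  g <- gammaProfile1d(r, s, gammaCriteria())
  expect_equal(max(g[5:25]), 1, tolerance = 0.05)
})

test_that("loosening criteria never increases gamma", {
  set.seed(32)
  A <- matrix(2 + runif(100), 10, 10)
  B <- A * (1 + 0.05 * matrix(rnorm(100), 10, 10))
  g1 <- gammaValues(gammaMap(A, B, gammaCriteria(dd = 3, dta = 1,
                                                 searchRadius = Inf)))
  g2 <- gammaValues(gammaMap(A, B, gammaCriteria(dd = 6, dta = 1,
                                                 searchRadius = Inf)))
  g3 <- gammaValues(gammaMap(A, B, gammaCriteria(dd = 3, dta = 2,
                                                 searchRadius = Inf)))
  expect_true(all(g2 <= g1 + 1e-12, na.rm = TRUE))
  expect_true(all(g3 <= g1 + 1e-12, na.rm = TRUE))
})

test_that("gamma is asymmetric in its arguments (regression fixture)", {
  # local normalization uses the reference dose: on uniform maps 4 and
  # 4.16, gamma(A,B) = 0.04/0.03 while gamma(B,A) = 0.04/(0.03 * 1.04)
  A <- matrix(4, 10, 10)
  B <- A * 1.04
  gAB <- gammaValues(gammaMap(A, B, gammaCriteria()))[5, 5]
  gBA <- gammaValues(gammaMap(B, A, gammaCriteria()))[5, 5]
  expect_equal(gAB, 4 / 3, tolerance = 1e-9)
  expect_equal(gBA, 4 / 3 / 1.04, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(gAB, gBA)))
})

test_that("passing rate honours cut-off, inclusion and exclusion masks", {
  # disagreement over rows 1:6; row 6 is rescued by the DTA (the
  # unmodified region is exactly 1 mm away), so rows 1:5 fail
  A <- matrix(4, 10, 10)
  B <- A
  B[1:6, ] <- A[1:6, ] * 1.10
  res <- gammaMap(A, B, gammaCriteria())
  expect_equal(passRate(res), 50)
  failMask <- matrix(FALSE, 10, 10); failMask[1:5, ] <- TRUE
  expect_equal(passingRate(res, exclude = failMask), 100)
  expect_equal(passingRate(res, include = failMask), 0)
  expect_error(passingRate(res, include = failMask & FALSE), "empty")
  # self comparison passes fully with or without masks
  self <- gammaMap(A, A, gammaCriteria())
  expect_equal(passingRate(self, exclude = failMask), 100)
  expect_equal(passingRate(self), 100)
})

test_that("rates are non-decreasing in the cut-off when failures sit low", {
  # low-dose half disagrees; raising the cut-off excludes it
  A <- outer(c(rep(1.5, 10), rep(6, 10)), rep(1, 20))
  B <- A
  B[1:10, ] <- A[1:10, ] * 1.2
  r1 <- gammaMap(A, B, gammaCriteria(cutoff = 1))
  r2 <- gammaMap(A, B, gammaCriteria(cutoff = 2))
  expect_gt(passRate(r2), passRate(r1))
})

test_that("reference-side resampling is available as a criteria flag", {
  set.seed(33)
  A <- matrix(3 + runif(64), 8, 8)
  B <- A * 1.01
  rEval <- gammaMap(A, B, gammaCriteria(resample = "evaluated"))
  rRef <- gammaMap(A, B, gammaCriteria(resample = "reference", step = 0.5))
  rBoth <- gammaMap(A, B, gammaCriteria(resample = "both", step = 0.5))
  expect_equal(length(gammaValues(rEval)), 64L)
  expect_gt(length(gammaValues(rRef)), 64L)   # reported on the fine raster
  expect_true(all(gammaValues(rBoth) <= 1, na.rm = TRUE))
})

test_that("degenerate gamma inputs are rejected", {
  A <- matrix(0.5, 5, 5)   # everything below the 1 Gy cut-off
  expect_error(gammaMap(A, A, gammaCriteria()), "empty evaluation set")
  expect_error(gammaCriteria(step = 2, dta = 1), "step must be <= DTA")
})
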