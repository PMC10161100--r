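test_that("density conversion reproduces the tabled worked examples", {
  # RW3, solid water and bone measured electron densities -> mass densities
  expect_equal(round(etaToRho(0.993), 3), 0.993)
  expect_equal(round(etaToRho(1.013), 3), 1.015)
  expect_equal(etaToRho(1.605), 1.7118, tolerance = 1e-4)
  expect_equal(etaToRho(1), 1)                   # both branches agree
  expect_equal((1 - 0.15) / 0.85, 1)             # continuity at eta = 1
})

test_that("eta-to-rho is continuous, monotone and the identity on [0, 1]", {
  eta <- seq(0, 2, by = 0.001)
  rho <- etaToRho(eta)
  expect_equal(rho[eta <= 1], eta[eta <= 1])
  expect_true(all(diff(rho) >= 0))
  expect_lt(max(abs(diff(rho))), 0.0015)         # no jump anywhere
  expect_error(etaToRho(-0.1), ">= 0")
})

test_that("HU interpolation hits breakpoints and interpolates linearly", {
  curve <- new("CalibrationCurve", hu = c(0, 1000), eta = c(1, 2))
  expect_identical(huToEta(c(0, 1000), curve), c(1, 2))
  expect_equal(huToEta(500, curve), 1.5)
  # out-of-range clamps
  expect_equal(huToEta(c(-5000, 5000), curve), c(1, 2))
})

test_that("HU interpolation equals a dense lookup-table oracle", {
  set.seed(4)
  hu <- sort(runif(7, -1000, 2000))
  eta <- cumsum(runif(7, 0, 0.5))
  curve <- new("CalibrationCurve", hu = hu, eta = eta)
  x <- runif(100, min(hu), max(hu))
  # oracle: dense table lookup at 0.01 HU resolution
  dense <- seq(min(hu), max(hu), by = 0.01)
  tab <- approx(hu, eta, xout = dense)$y
  oracle <- tab[pmin(length(dense),
                     pmax(1, round((x - min(hu)) / 0.01) + 1))]
  expect_equal(huToEta(x, curve), oracle, tolerance = 1e-5)
  # and exactly against direct linear interpolation at higher precision
  expect_equal(huToEta(x, curve), approx(hu, eta, xout = x)$y,
               tolerance = 1e-9)
})

test_that("synthesized CT round-trips each material's electron density", {
  lab <- coarsePhantom()
  mats <- materialTable()
  curve <- defaultCurve()
  ct <- synthesizeCT(lab, mats, curve, noiseSd = 0)
  eta <- huToEta(ct, curve)
  for (m in c("lgk_sw", "rw3", "bone", "air")) {
    sel <- voxels(lab) == match(m, lab@materials)
    expect_lt(max(abs(voxels(eta)[sel] -
                        materialProperty(mats, m, "eta"))), 1e-6)
  }
})

test_that("identity-like curve maps water to HU 0 and CT noise is faithful", {
  lab <- coarsePhantom()
  mats <- materialTable()
  curve <- new("CalibrationCurve", hu = c(-1000, 0, 1000),
               eta = c(0, 1, 2))  # HU = 1000 (eta - 1)
  ct0 <- synthesizeCT(lab, mats, curve, noiseSd = 0)
  water <- abs(voxels(ct0)[voxels(lab) == match("lgk_sw", lab@materials)] -
                 1000 * (1.013 - 1))
  expect_lt(max(water), 1e-9)
  ct <- synthesizeCT(lab, mats, curve, noiseSd = 20, seed = 11)
  sel <- voxels(lab) == match("lgk_sw", lab@materials)
  expect_gt(sum(sel), 1e5)
  expect_equal(sd(voxels(ct)[sel]), 20, tolerance = 0.03)
  # bit-reproducible under a fixed seed
  ct2 <- synthesizeCT(lab, mats, curve, noiseSd = 20, seed = 11)
  expect_identical(voxels(ct), voxels(ct2))
})

test_that("density maps recover material densities, also under HU noise", {
  lab <- coarsePhantom()
  mats <- materialTable()
  curve <- defaultCurve()
  ct0 <- synthesizeCT(lab, mats, curve, noiseSd = 0)
  maps0 <- buildDensityMaps(ct0, curve)
  ctN <- synthesizeCT(lab, mats, curve, noiseSd = 20, seed = 3)
  mapsN <- buildDensityMaps(ctN, curve)
  for (m in c("lgk_sw", "rw3", "bone")) {
    sel <- voxels(lab) == match(m, lab@materials)
    truth <- etaToRho(materialProperty(mats, m, "eta"))
    expect_equal(mean(voxels(maps0@rho)[sel]), truth, tolerance = 1e-6,
                 label = m)
    expect_gt(sum(sel), 1e3)
    expect_equal(mean(voxels(mapsN@rho)[sel]), truth, tolerance = 0.005,
                 label = paste0(m, " (noisy)"))
  }
})

test_that("all-water CT yields unit density everywhere", {
  ct <- voxelGrid(array(0, c(5, 5, 5)), spacing = 1, origin = c(0, 0, 0))
  maps <- buildDensityMaps(ct, defaultCurve())
  expect_true(all(voxels(maps@eta) == 1))
  expect_true(all(voxels(maps@rho) == 1))
})

test_that("composition bins are density-consistent and mass fractions sum to 1", {
  expect_equal(compositionBins()$name[rhoToComposition(0.0012)], "air")
  expect_equal(compositionBins()$name[rhoToComposition(1.0)], "soft")
  expect_equal(compositionBins()$name[rhoToComposition(1.72)], "bone")
  for (comp in compositionBins()$composition)
    expect_equal(sum(comp), 1, tolerance = 1e-6)
})

test_that("electron densities outside the curve are rejected unless metal", {
  lab <- coarsePhantom()
  mats <- materialTable()
  mats@table$eta[mats@table$material == "bone"] <- 5  # beyond curve, not metal
  expect_error(synthesizeCT(lab, mats, defaultCurve()), "bone")
  # metal passes through as the plateau
  ct <- synthesizeCT(lab, materialTable(), defaultCurve(), metalHU = 3000)
  pin <- voxels(ct)[voxels(lab) == match("metal", lab@materials)]
  if (length(pin)) expect_true(all(pin == 3000))
})
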