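#' Default configuration of the end-to-end verification run
#'
#' The study conditions: the inhomogeneous phantom at CT spacing
#' (0.53, 0.53, 1) mm, the reference single 16 mm shot (4 Gy at the 50%
#' isodose), film at 0.169 mm/px on the axial plane through the unit
#' centre point, 3%/1 mm local gamma with a 1 Gy cut-off, and the packaged
#' K_med table. Every stage's knobs are exposed here.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param plan a [Plan-class].
#' @param ctNoiseSd HU noise of the synthetic CT.
#' @param filmNoise relative film measurement noise.
#' @param applyKmed apply the dose-to-medium conversion to the film.
#' @param mclite include the stochastic engine as a second reference
#'   (list(enabled, nHistories, nBatches)).
#' @param phantomSpacing CT voxel spacing mm.
#' @param filmSize film extent mm (must cover the fiducial pins).
#' @param doseSpacing dose-grid voxel size mm (default 1).
#' @param criteria a [GammaCriteria-class].
#' @return config list for [runVerification()].
#' @export
verificationConfig <- function(seed = 1L, plan = singleShotPlan(),
                               ctNoiseSd = 0, filmNoise = 0,
                               applyKmed = TRUE,
                               mclite = list(enabled = TRUE,
                                             nHistories = 2e5,
                                             nBatches = 10),
                               phantomSpacing = c(0.53, 0.53, 1),
                               filmSize = c(150, 150),
                               doseSpacing = 1,
                               criteria = gammaCriteria()) {
  list(seed = as.integer(seed), plan = plan, ctNoiseSd = ctNoiseSd,
       filmNoise = filmNoise, applyKmed = applyKmed, mclite = mclite,
       phantomSpacing = phantomSpacing, filmSize = filmSize,
       doseSpacing = doseSpacing, criteria = criteria)
}

#' Run the end-to-end dosimetric verification pipeline
#'
#' Orchestrates phantom voxelization, CT synthesis, density calibration,
#' deterministic (and optionally stochastic) dose calculation, film
#' simulation, pin/hole detection and rigid registration, dose-to-medium
#' conversion and gamma analysis, and assembles the passing-rate table
#' (reference source x with/without the air-cavity mask) plus the
#' uncertainty budgets. All randomness derives from the config seed; a
#' rerun with the same config is byte-identical.
#'
#' @param config list from [verificationConfig()].
#' @return a [VerificationReport-class].
#' @export
runVerification <- function(config = verificationConfig()) {
  t0 <- Sys.time()
  logln <- character(0)
  stamp <- function(...) {
    msg <- sprintf(...)
    logln <<- c(logln, msg)  # report log carries no wall times (rerun
    message(sprintf("[%6.1fs] %s",  # determinism); timings go to stderr
                    as.numeric(Sys.time() - t0, units = "secs"), msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- config$seed
  plan <- config$plan

  stamp("phantom: voxelizing at (%s) mm",
        paste(config$phantomSpacing, collapse = ", "))
  spec <- phantomSpec(spacing = config$phantomSpacing)
  labels <- stage("build_phantom", buildPhantom(spec))
  materials <- materialTable()
  curve <- defaultCurve()

  stamp("ct: synthesizing (noise sd %.3g HU)", config$ctNoiseSd)
  ct <- stage("synthesize_ct",
              synthesizeCT(labels, materials, curve,
                           noiseSd = config$ctNoiseSd, seed = seed + 1L))
  maps <- stage("densities", buildDensityMaps(ct, curve, pathway = "lgp"))

  # dose grid covering the film plane region
  ctr <- colMeans(do.call(rbind, lapply(plan@shots, function(s) s@center)))
  half <- config$filmSize / 2 + 5
  dsp <- config$doseSpacing %||% 1
  gs <- list(origin = c(ctr[1] - half[1], ctr[2] - half[2], ctr[3] - 15),
             spacing = rep(dsp, 3),
             dims = as.integer(c(2 * half / dsp, 30 / dsp)) + 1L)
  stamp("dose: deterministic engine on %d x %d x %d grid",
        gs$dims[1], gs$dims[2], gs$dims[3])
  dose <- stage("compute_plan_dose",
                computePlanDose(plan, maps, gridSpec = gs))
  calib <- attr(dose, "calibration")
  plan@bot <- calib$bot
  stamp("dose: BOT %.3f min, max %.3f Gy", calib$bot, max(dose@voxels))

  mcDose <- NULL
  if (isTRUE(config$mclite$enabled)) {
    stamp("dose: MC-lite with %g histories", config$mclite$nHistories)
    mcDose <- stage("mc_lite_dose",
                    mcLiteDose(plan, maps,
                               nHistories = config$mclite$nHistories,
                               nBatches = config$mclite$nBatches,
                               seed = seed + 2L, gridSpec = gs))
  }

  stamp("film: simulating at 0.169 mm/px (noise %.3g)", config$filmNoise)
  plane <- filmPlane(origin = c(ctr[1], ctr[2], 100))
  kmedTab <- defaultKmedTable()
  fs <- planFieldSizes(plan)
  factors <- c(bone = planAverageKmed(kmedTab, "bone", fs),
               air = planAverageKmed(kmedTab, "air", fs))
  protoFilm <- simulateFilm(dose, plane, sizeMm = config$filmSize,
                            pins = spec@pins, seed = seed + 3L)
  respMasks <- regionMasksOnFilm(labels, protoFilm)
  film <- stage("simulate_film",
                simulateFilm(dose, plane, sizeMm = config$filmSize,
                             noiseFraction = config$filmNoise,
                             pins = spec@pins, seed = seed + 3L,
                             response = list(masks = respMasks,
                                             factors = factors)))

  stamp("registration: pins and holes")
  pins <- stage("detect_pins", detectPinCentroidsCT(ct))
  holes2d <- stage("detect_holes", detectHoleCentroidsFilm(film))
  holes3d <- matrix(plane$origin, 3, 3, byrow = TRUE) +
    holes2d[, 1] %o% plane$ex + holes2d[, 2] %o% plane$ey
  reg <- stage("fit_rigid", fitRigid(fixed = holes3d, moving = pins))
  stamp("registration: RMS %.4f mm", attr(reg, "rms"))
  tps <- stage("resample", resampleDoseToFilm(dose, reg, film))

  filmDm <- film
  if (isTRUE(config$applyKmed)) {
    stamp("kmed: bone %.3f, air %.3f", factors[["bone"]], factors[["air"]])
    filmDm <- stage("apply_kmed",
                    applyKmed(film, respMasks, as.list(factors)))
  }

  stamp("gamma: %g%%/%g mm, cutoff %g Gy", config$criteria@dd,
        config$criteria@dta, config$criteria@cutoff)
  holeMask <- film@pixels <= 0
  gmFilm <- stage("gamma_map",
                  gammaMap(filmDm, tps, config$criteria,
                           includeMask = !holeMask))
  airMask <- respMasks$air
  rates <- data.frame(
    reference = "film",
    excludingAir = passingRate(gmFilm, exclude = airMask),
    includingAir = passingRate(gmFilm))
  gmMc <- NULL
  if (!is.null(mcDose)) {
    mcFilm <- resampleDoseToFilm(mcDose, identityTransform(), film)
    gmMc <- stage("gamma_map_mc",
                  gammaMap(mcFilm, tps, config$criteria,
                           includeMask = !holeMask))
    rates <- rbind(rates, data.frame(
      reference = "mclite",
      excludingAir = passingRate(gmMc, exclude = airMask),
      includingAir = passingRate(gmMc)))
  }
  for (i in seq_len(nrow(rates)))
    stamp("gamma[%s]: %.1f%% excluding air, %.1f%% including air",
          rates$reference[i], rates$excludingAir[i], rates$includingAir[i])

  rep <- new("VerificationReport", rates = rates,
             kmed = as.list(factors), budgets = defaultBudgets(),
             seed = as.numeric(seed),
             config = list(ctNoiseSd = config$ctNoiseSd,
                           filmNoise = config$filmNoise,
                           applyKmed = config$applyKmed,
                           bot = calib$bot,
                           prescription = plan@prescriptionDose,
                           isodose = plan@prescriptionIsodose),
             log = logln)
  attr(rep, "gamma") <- list(film = gmFilm, mclite = gmMc)
  rep
}

#' Write a verification report as JSON (+ CSV rate table)
#'
#' @param report a [VerificationReport-class].
#' @param path JSON path; the rate table is also written next to it as
#'   `<path>.rates.csv`.
#' @export
writeReportJson <- function(report, path) {
  budgets <- lapply(report@budgets, function(b)
    list(label = b@label, combined = b@combined,
         display = displayPercent(b@combined),
         components = b@components))
  jsonlite::write_json(
    list(rates = report@rates, kmed = report@kmed, budgets = budgets,
         seed = report@seed, config = report@config, log = report@log),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(report@rates, paste0(path, ".rates.csv"), row.names = FALSE)
  invisible(path)
}

setMethod("show", "VerificationReport", function(object) {
  cat("VerificationReport\n")
  cat(sprintf("  BOT %.3f min, prescription %g Gy at %g%%\n",
              object@config$bot, object@config$prescription,
              object@config$isodose))
  cat(sprintf("  K_med: bone %.3f, air %.3f\n",
              object@kmed$bone, object@kmed$air))
  print(object@rates, row.names = FALSE)
})
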