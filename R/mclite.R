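#' Stochastic kernel dose engine (MC-lite)
#'
#' Photon-ray energy deposition engine sampling (shot, sector) categories
#' from the sector sampling distribution ([sectorProbabilities()]), a source
#' uniformly among the sector's 24, and an aim point uniformly in the focal
#' disc of the active collimator. Each ray deposits
#' exp(-mu d_rad) x step / voxel-volume along its path with at most one
#' stochastic first-scatter redirect at an exponentially sampled
#' radiological depth. There is no electron transport: the air-cavity
#' disequilibrium of a full Monte Carlo is reproduced only qualitatively.
#'
#' Per-history scores are converted to Gy with the absolute scaling factor
#' F = refRate / refPerHistory x BOT, where refPerHistory is the engine's
#' own per-history dose at the UCP of the reference 16 mm / water-sphere
#' configuration (computed with the same history budget when not supplied).
#' Per-voxel relative statistical uncertainty comes from the batch method
#' (standard error of batch means).
#'
#' @param plan a [Plan-class] with its beam-on time set (`plan@bot`,
#'   minutes), e.g. from the deterministic engine's calibration attribute.
#' @param maps a [DensityMaps-class].
#' @param machine a [MachineModel-class].
#' @param nHistories total photon histories (>= nBatches).
#' @param nBatches batches for the uncertainty estimate (>= 2).
#' @param seed integer seed; the dose grid is bit-reproducible.
#' @param gridSpec output grid, as in [computePlanDose()].
#' @param traceSpacing density-grid spacing for transport, mm.
#' @param refPerHistory optional list(value, se): per-history UCP dose of
#'   the reference configuration, to reuse across calls.
#' @param phspCounts per-collimator phase-space counts for
#'   [sectorProbabilities()].
#' @return a [DoseGrid-class] (dose-to-medium) with per-voxel relative
#'   uncertainties; attribute `mc` holds list(sampling, counts,
#'   refPerHistory, ucpSe, F).
#' @export
mcLiteDose <- function(plan, maps, machine = defaultMachine(),
                       nHistories = 1e5, nBatches = 10, seed = 1L,
                       gridSpec = NULL, traceSpacing = 1,
                       refPerHistory = NULL,
                       phspCounts = c("4" = 1, "8" = 1, "16" = 1)) {
  if (nBatches < 2 || nHistories < nBatches)
    stop("need nHistories >= nBatches >= 2")
  if (is.na(plan@bot))
    stop("plan has no beam-on time; set plan@bot (e.g. from the ",
         "deterministic engine's calibration attribute)")
  gs <- if (is.null(gridSpec)) .defaultGridSpec(plan) else gridSpec
  rhoTrace <- if (all(abs(maps@rho@spacing - traceSpacing) < 1e-12))
    maps@rho else resampleGrid(maps@rho, traceSpacing)
  set.seed(as.integer(seed))
  run <- .mcRun(plan, rhoTrace, machine, gs, nHistories, nBatches,
                phspCounts)
  if (is.null(refPerHistory)) {
    refPlan <- singleShotPlan()
    # score the reference UCP dose in the same voxel size as the plan run,
    # so the two per-history estimates share their volume averaging
    refGs <- .defaultGridSpec(refPlan, spacing = gs$spacing[1])
    refRun <- .mcRun(refPlan, .waterSphereRho(spacing = traceSpacing),
                     machine, refGs, nHistories, nBatches, phspCounts)
    g <- voxelGrid(refRun$mean, refGs$spacing, refGs$origin)
    gse <- voxelGrid(refRun$se, refGs$spacing, refGs$origin)
    refPerHistory <- list(value = sampleGrid(g, matrix(c(100, 100, 100), 1)),
                          se = sampleGrid(gse, matrix(c(100, 100, 100), 1)))
  }
  F <- plan@refRate / refPerHistory$value * plan@bot
  dose <- run$mean * F
  relU <- array(0, dim(run$mean))
  pos <- run$mean > 0
  relU[pos] <- run$se[pos] / run$mean[pos]
  out <- new("DoseGrid", voxels = dose, spacing = gs$spacing,
             origin = gs$origin, medium = "medium", uncertainty = relU)
  ucp <- sampleGrid(voxelGrid(run$se, gs$spacing, gs$origin),
                    matrix(c(100, 100, 100), 1))
  attr(out, "mc") <- list(sampling = run$sampling, counts = run$counts,
                          refPerHistory = refPerHistory,
                          ucpSe = ucp * F, F = F)
  out
}

.mcRun <- function(plan, rhoTrace, machine, gs, nHistories, nBatches,
                   phspCounts) {
  sampling <- sectorProbabilities(plan, phspCounts)
  tb <- sampling@table
  cl <- machine@collimators[match(tb$collimator, machine@collimators$size), ]
  ctr <- do.call(rbind, lapply(plan@shots, function(s) s@center))
  cat <- cbind(tb$sector - 1, ctr[tb$shot, 1], ctr[tb$shot, 2],
               ctr[tb$shot, 3], cl$fieldRadius, cl$outputFactor, cl$mu)
  res <- cpp_mc_lite(as.numeric(rhoTrace@voxels), dim(rhoTrace@voxels),
                     rhoTrace@spacing, rhoTrace@origin,
                     as.matrix(machine@sources[, c("x", "y", "z")]), 24L,
                     cat, tb$p, gs$dims, gs$spacing, gs$origin,
                     nHistories, as.integer(nBatches))
  list(mean = array(res$mean, gs$dims), se = array(res$se, gs$dims),
       counts = res$counts, sampling = sampling)
}
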