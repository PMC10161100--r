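.gkCache <- new.env(parent = emptyenv())

#' Radiological path length between two points
#'
#' Exact voxel-traversal line integral of mass density along the segment
#' (parametric Siddon-style traversal), in g/cm2. Segments not intersecting
#' the grid (or of zero length) integrate to 0.
#'
#' @param rho [VoxelGrid-class] of mass density, g/cm3.
#' @param p0,p1 segment endpoints, mm (vectors or n x 3 matrices).
#' @return radiological depth(s), g/cm2.
#' @examples
#' g <- voxelGrid(array(1, c(10, 10, 10)), spacing = 10, origin = c(5, 5, 5))
#' radiologicalDepth(g, c(0, 50, 50), c(100, 50, 50))  # 10 cm water -> 10
#' @export
radiologicalDepth <- function(rho, p0, p1) {
  P0 <- matrix(as.numeric(p0), ncol = 3)
  P1 <- matrix(as.numeric(p1), ncol = 3)
  d <- cpp_rad_depth(as.numeric(rho@voxels), dim(rho@voxels), rho@spacing,
                     rho@origin, P0, P1)
  if (length(d) == 1L) d[[1]] else d
}

.collimatorRow <- function(machine, collimator) {
  i <- match(as.numeric(collimator), machine@collimators$size)
  if (is.na(i)) stop("unknown collimator: ", collimator)
  machine@collimators[i, ]
}

#' Relative primary dose of a single beam at a point
#'
#' Primary model of the deterministic engine: inverse-square from the
#' source, exponential attenuation over the radiological depth, and an
#' error-function penumbra evaluated at the off-axis distance projected to
#' the focal plane, with the penumbra width scaled by the ratio of
#' radiological to geometric depth.
#'
#' @param point evaluation point, mm.
#' @param source source position, mm.
#' @param collimator 4, 8 or 16.
#' @param rho density [VoxelGrid-class].
#' @param machine a [MachineModel-class].
#' @param aim aim point (defaults to the machine focus).
#' @return relative dose (unitless).
#' @export
beamDose <- function(point, source, collimator, rho, machine = defaultMachine(),
                     aim = machine@focus) {
  cl <- .collimatorRow(machine, collimator)
  par <- cbind(cl$outputFactor, cl$mu, cl$fieldRadius, cl$sigma, 1)
  v <- cpp_primary_dose(as.numeric(rho@voxels), dim(rho@voxels), rho@spacing,
                        rho@origin, matrix(source, 1), matrix(aim, 1), par,
                        c(1L, 1L, 1L), c(1, 1, 1), as.numeric(point))
  v[[1]]
}

# beams of a plan as matrices for the C++ kernel: sources translated so the
# shot centre plays the focus
.planBeams <- function(plan, machine) {
  spos <- aim <- NULL
  par <- NULL
  src <- as.matrix(machine@sources[, c("x", "y", "z")])
  for (sh in plan@shots) {
    off <- sh@center - machine@focus
    for (sec in 1:8) {
      st <- sh@sectors[sec]
      if (st == "blocked" || sh@weight == 0) next
      cl <- .collimatorRow(machine, st)
      rows <- which(machine@sources$sector == sec)
      spos <- rbind(spos, sweep(src[rows, , drop = FALSE], 2, -off))
      aim <- rbind(aim, matrix(sh@center, length(rows), 3, byrow = TRUE))
      par <- rbind(par, matrix(c(cl$outputFactor, cl$mu, cl$fieldRadius,
                                 cl$sigma, sh@weight),
                               length(rows), 5, byrow = TRUE))
    }
  }
  if (is.null(spos)) stop("plan has no active beams")
  list(spos = spos, aim = aim, par = par)
}

# default dose-grid geometry: shot bounding box + margin, 1 mm voxels
.defaultGridSpec <- function(plan, spacing = 1, margin = 30) {
  ctr <- do.call(rbind, lapply(plan@shots, function(s) s@center))
  lo <- apply(ctr, 2, min) - margin
  hi <- apply(ctr, 2, max) + margin
  n <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(origin = lo, spacing = rep(spacing, 3), dims = n)
}

# 3D FFT convolution with a normalized isotropic exponential kernel
.scatterConvolve <- function(arr, spacing, range_mm) {
  d <- dim(arr)
  kr <- pmin(d, as.integer(ceiling(3 * range_mm / spacing)) + 1L)
  np <- vapply(1:3, function(a) stats::nextn(d[a] + 2L * kr[a], c(2, 3)), 1)
  ax <- lapply(1:3, function(a) {
    i <- seq_len(np[a]) - 1
    i <- ifelse(i > np[a] / 2, i - np[a], i)  # wrap-around distances
    (i * spacing[a])^2
  })
  r <- sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+"))
  K <- exp(-r / range_mm)
  K <- K / sum(K)
  A <- array(0, np)
  A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  conv <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / prod(np)
  conv[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

#' Density maps of the reference water sphere
#'
#' The 160 mm homogeneous water sphere used for absolute calibration
#' (unit density inside, ambient air outside), as [DensityMaps-class].
#' @param spacing voxel spacing mm.
#' @return a [DensityMaps-class].
#' @export
waterSphereMaps <- function(spacing = 1) {
  rho <- .waterSphereRho(spacing = spacing)
  new("DensityMaps", eta = rho, rho = rho,
      bin = voxelGrid(array(rhoToComposition(as.vector(rho@voxels)),
                            dim(rho@voxels)),
                      spacing = rho@spacing, origin = rho@origin))
}

# water-sphere density grid (160 mm sphere of unit density in ambient air)
.waterSphereRho <- function(spacing = 1, diameter = 160, margin = 5) {
  r <- diameter / 2
  lo <- 100 - r - margin
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  n <- as.integer(ceiling((2 * r + 2 * margin) / spacing)) + 1L
  ax <- lapply(1:3, function(a) lo + (seq_len(n[a]) - 1) * spacing[a])
  d2 <- outer(outer((ax[[1]] - 100)^2, (ax[[2]] - 100)^2, "+"),
              (ax[[3]] - 100)^2, "+")
  rho <- array(0.0012, n)
  rho[d2 <= r^2] <- 1
  voxelGrid(rho, spacing = spacing, origin = rep(lo, 3))
}

# relative dose field of a beam set (primary + CC-lite scatter)
.relativeDose <- function(beams, rhoTrace, gridSpec, machine, scatter = TRUE) {
  rel <- cpp_primary_dose(as.numeric(rhoTrace@voxels), dim(rhoTrace@voxels),
                          rhoTrace@spacing, rhoTrace@origin,
                          beams$spos, beams$aim, beams$par,
                          gridSpec$dims, gridSpec$spacing, gridSpec$origin)
  rel <- array(rel, gridSpec$dims)
  if (scatter) {
    w <- beams$par[, 1] * beams$par[, 5]
    # effective kernel amplitude/range: beam-weighted collimator values,
    # range scaled by the mean density of the computation region
    sizes <- machine@collimators$size[match(beams$par[, 3],
                                            machine@collimators$fieldRadius)]
    amp <- sum(machine@collimators$scatterAmp[match(sizes,
             machine@collimators$size)] * w) / sum(w)
    rng <- sum(machine@collimators$scatterRange[match(sizes,
             machine@collimators$size)] * w) / sum(w)
    mrho <- max(mean(sampleGrid(rhoTrace,
      as.matrix(expand.grid(
        x = gridSpec$origin[1] + c(0.25, 0.75) * (gridSpec$dims[1] - 1) * gridSpec$spacing[1],
        y = gridSpec$origin[2] + c(0.25, 0.75) * (gridSpec$dims[2] - 1) * gridSpec$spacing[2],
        z = gridSpec$origin[3] + c(0.25, 0.75) * (gridSpec$dims[3] - 1) * gridSpec$spacing[3])))),
      0.1)
    rel <- rel + amp * .scatterConvolve(rel, gridSpec$spacing, rng / mrho)
  }
  rel
}

# relative dose at the UCP for the reference configuration (16 mm shot,
# homogeneous water sphere), memoised per machine/grid geometry
.referenceRelative <- function(machine, spacing, traceSpacing, scatter) {
  key <- paste(c(machine@sfd, machine@collimators$outputFactor,
                 machine@collimators$sigma, machine@collimators$mu,
                 machine@collimators$scatterAmp,
                 machine@collimators$scatterRange,
                 spacing, traceSpacing, scatter), collapse = "|")
  hit <- .gkCache[[key]]
  if (!is.null(hit)) return(hit)
  refPlan <- singleShotPlan()
  gs <- .defaultGridSpec(refPlan, spacing = spacing[1])
  rhoTrace <- .waterSphereRho(spacing = traceSpacing)
  beams <- .planBeams(refPlan, machine)
  rel <- .relativeDose(beams, rhoTrace, gs, machine, scatter)
  ucp <- voxelGrid(rel, gs$spacing, gs$origin)
  val <- sampleGrid(ucp, matrix(c(100, 100, 100), 1))
  .gkCache[[key]] <- val
  val
}

#' Compute the absolute 3D dose of a plan (deterministic engine)
#'
#' Convolution-style kernel engine: per-beam primary dose (inverse square,
#' exponential attenuation over the radiological depth through the density
#' maps, error-function penumbra with depth-scaled width) summed over all
#' active sources of all shots, plus a collapsed-cone-lite scatter term
#' (primary convolved with an isotropic exponential kernel whose range is
#' scaled by the density of the computation region). The relative field is
#' normalized to the prescription and tied to absolute dose through the
#' decay-corrected reference dose rate: the engine's relative dose at the
#' UCP of the reference 16 mm / water-sphere configuration corresponds to
#' `plan@refRate` Gy/min, so that the UCP dose of the reference
#' configuration equals rate x beam-on time (calibration closure).
#'
#' @param plan a [Plan-class].
#' @param maps a [DensityMaps-class].
#' @param machine a [MachineModel-class].
#' @param gridSpec list(origin, spacing, dims) of the output dose grid;
#'   default: shot bounding box + 30 mm margin at 1 mm.
#' @param traceSpacing spacing (mm) of the density grid used for ray
#'   tracing (density maps are resampled; default 1 mm isotropic).
#' @param scatter include the scatter term.
#' @return a [DoseGrid-class] (dose-to-medium) with a `calibration`
#'   attribute: list(scale, bot, refRel, F).
#' @export
computePlanDose <- function(plan, maps, machine = defaultMachine(),
                            gridSpec = NULL, traceSpacing = 1,
                            scatter = TRUE) {
  if (!length(plan@shots)) stop("empty plan")
  if (is.null(gridSpec)) gs <- .defaultGridSpec(plan)
  else gs <- gridSpec
  rhoTrace <- if (is.null(traceSpacing) ||
                  all(abs(maps@rho@spacing - traceSpacing) < 1e-12))
    maps@rho else resampleGrid(maps@rho, traceSpacing)
  beams <- .planBeams(plan, machine)
  rel <- .relativeDose(beams, rhoTrace, gs, machine, scatter)
  refRel <- .referenceRelative(machine, gs$spacing, rhoTrace@spacing[1],
                               scatter)
  norm <- normalizePrescription(voxelGrid(rel, gs$spacing, gs$origin),
                                plan, refRel)
  dose <- rel * norm$scale
  out <- new("DoseGrid", voxels = dose, spacing = gs$spacing,
             origin = gs$origin, medium = "medium", uncertainty = NULL)
  attr(out, "calibration") <- list(
    scale = norm$scale, bot = norm$bot, refRel = refRel,
    F = plan@refRate / refRel * norm$bot)
  out
}
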