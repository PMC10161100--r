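#' @import methods
#' @importFrom stats fft rnorm runif approx sd quantile setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom Rcpp sourceCpp
#' @useDynLib gkverify, .registration = TRUE
NULL

#' Axis-aligned 3D scalar grid in Leksell mm coordinates
#'
#' The central container of the package: a 3D array of scalar values (CT
#' number, density or dose) stored x-fastest, together with the voxel spacing
#' and the world coordinate of the centre of voxel `[1,1,1]`. The Leksell
#' stereotactic frame is used throughout; the machine focus (unit centre
#' point, UCP) sits at (100, 100, 100) mm. Voxels are half-open boxes
#' centred on their sample point.
#'
#' @slot voxels 3D numeric (or integer) array, dimensions (nx, ny, nz).
#' @slot spacing voxel spacing in mm, length 3, strictly positive.
#' @slot origin world mm coordinate of the centre of voxel `[1,1,1]`.
#' @export
setClass("VoxelGrid",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values")
    if (length(object@origin) != 3L) return("origin must have length 3")
    TRUE
  })

#' Material label grid
#'
#' A [VoxelGrid-class] whose voxels are integer codes into a vector of
#' material names; every voxel carries exactly one label.
#'
#' @slot materials character vector of material names; voxel value k means
#'   `materials[k]`.
#' @export
setClass("LabelGrid", contains = "VoxelGrid",
  representation(materials = "character"),
  validity = function(object) {
    v <- object@voxels
    if (anyNA(v)) return("every voxel must carry a label")
    if (min(v) < 1 || max(v) > length(object@materials))
      return("label codes outside the material table")
    TRUE
  })

#' Dose grid with reporting-medium flag
#'
#' @slot medium `"water"` or `"medium"` (dose-to-water vs dose-to-medium).
#' @slot uncertainty per-voxel relative statistical uncertainty (stochastic
#'   engine only), same dimensions as the dose array, or `NULL`.
#' @export
setClass("DoseGrid", contains = "VoxelGrid",
  representation(medium = "character", uncertainty = "ANY"),
  prototype(medium = "medium", uncertainty = NULL),
  validity = function(object) {
    if (!object@medium %in% c("water", "medium"))
      return("medium must be 'water' or 'medium'")
    if (min(object@voxels) < -1e-9) return("dose must be non-negative")
    if (!is.null(object@uncertainty) &&
        !identical(dim(object@uncertainty), dim(object@voxels)))
      return("uncertainty must match the dose dimensions")
    TRUE
  })

#' Geometry of the inhomogeneous solid-water sphere phantom
#'
#' Describes the 160 mm solid-water sphere whose central slabs carry a
#' mirrored-C bone inset (6 cm long in z, 1 cm thick in y, 1.5 cm thick in
#' x), a 2 x 2 x 6 cm RW3 core, a 1.5 x 2 x 6 cm air cavity and three metal
#' fiducial pins. Boxes are axis-aligned, given as `list(low =, high =)` in
#' mm, half-open on the high side.
#'
#' @slot sphereDiameter mm (default 160).
#' @slot coreBox,airBox axis-aligned boxes (RW3 core; air cavity).
#' @slot boneBoxes list of boxes forming the mirrored C.
#' @slot pins 3 x 3 matrix of pin positions (mm, rows are points).
#' @slot materialOf named character map region -> material name.
#' @slot spacing CT voxel spacing mm (default 0.53, 0.53, 1).
#' @slot margin extra grid margin beyond the sphere, mm.
#' @export
setClass("PhantomSpec",
  representation(sphereDiameter = "numeric", coreBox = "list",
                 airBox = "list", boneBoxes = "list", pins = "matrix",
                 materialOf = "character", spacing = "numeric",
                 margin = "numeric"),
  validity = function(object) {
    if (nrow(object@pins) != 3L) return("exactly 3 pins required")
    if (any(object@spacing <= 0)) return("spacing must be strictly positive")
    r <- object@sphereDiameter / 2
    boxes <- c(list(object@coreBox, object@airBox), object@boneBoxes)
    for (b in boxes) {
      corners <- as.matrix(expand.grid(
        x = c(b$low[1], b$high[1]), y = c(b$low[2], b$high[2]),
        z = c(b$low[3], b$high[3])))
      if (any(sqrt(rowSums(sweep(corners, 2, c(100, 100, 100))^2)) > r + 1e-9))
        return("all boxes must lie inside the sphere")
    }
    ov <- function(a, b) all(a$low < b$high - 1e-9 & b$low < a$high - 1e-9)
    if (ov(object@airBox, object@coreBox))
      return("air_box overlaps core_box")
    for (b in object@boneBoxes)
      if (ov(b, object@coreBox)) return("bone box overlaps core_box")
    TRUE
  })

#' Material properties table
#'
#' Nominal mass density, relative electron density and elemental composition
#' (mass fractions) per material. Metal materials are flagged: they sit
#' outside any CT calibration curve and synthesize at a fixed HU plateau.
#'
#' @slot table data.frame with columns material, rho (g/cm3), eta, metal.
#' @slot composition named list of named mass-fraction vectors.
#' @export
setClass("MaterialTable",
  representation(table = "data.frame", composition = "list"),
  validity = function(object) {
    tb <- object@table
    if (!all(c("material", "rho", "eta", "metal") %in% names(tb)))
      return("table needs columns material, rho, eta, metal")
    if (any(tb$rho <= 0) || any(tb$eta <= 0))
      return("rho and eta must be positive")
    for (nm in names(object@composition)) {
      s <- sum(object@composition[[nm]])
      if (abs(s - 1) > 1e-6)
        return(sprintf("mass fractions of '%s' sum to %.8f, not 1", nm, s))
    }
    TRUE
  })

#' HU to density calibration curve
#'
#' Ordered breakpoints for the HU to relative-electron-density map, with
#' optional separate breakpoints for the HU to mass-density map used on the
#' Monte Carlo pathway. Interpolation is piecewise linear; out-of-range HU
#' clamp to the end values.
#'
#' @slot hu,eta breakpoints of the HU -> eta map.
#' @slot huRho,rho optional breakpoints of the HU -> rho map (may be empty).
#' @export
setClass("CalibrationCurve",
  representation(hu = "numeric", eta = "numeric",
                 huRho = "numeric", rho = "numeric"),
  prototype(huRho = numeric(0), rho = numeric(0)),
  validity = function(object) {
    if (length(object@hu) < 2L) return("need at least 2 breakpoints")
    if (length(object@hu) != length(object@eta))
      return("hu and eta lengths differ")
    if (any(diff(object@hu) <= 0)) return("HU must be strictly increasing")
    if (any(object@eta < 0) || any(diff(object@eta) < 0))
      return("eta must be non-negative and non-decreasing")
    if (length(object@huRho)) {
      if (length(object@huRho) != length(object@rho))
        return("huRho and rho lengths differ")
      if (any(diff(object@huRho) <= 0) || any(object@rho < 0))
        return("invalid HU -> rho breakpoints")
    }
    TRUE
  })

#' Per-voxel density maps
#'
#' Relative electron density, mass density and composition-bin grids sharing
#' the source CT geometry.
#' @slot eta,rho,bin [VoxelGrid-class] grids (bin holds integer indices into
#'   the packaged tissue-composition bins).
#' @export
setClass("DensityMaps",
  representation(eta = "VoxelGrid", rho = "VoxelGrid", bin = "VoxelGrid"),
  validity = function(object) {
    if (!identical(dim(object@eta@voxels), dim(object@rho@voxels)))
      return("eta and rho grids must share geometry")
    TRUE
  })

#' Source and collimator geometry of the radiosurgery unit
#'
#' 8 sectors x 24 sources = 192 cobalt sources on latitude rings of a cone,
#' all aimed at the focus, plus per-collimator (4/8/16 mm) beam parameters.
#'
#' @slot sources data.frame: sector, x, y, z (mm).
#' @slot collimators data.frame: size (mm), fieldRadius (mm at focus),
#'   outputFactor (16 mm = 1), mu (cm2/g), sigma (mm penumbra),
#'   scatterAmp, scatterRange (mm).
#' @slot focus focus point mm (UCP).
#' @slot sfd source-focus distance mm.
#' @export
setClass("MachineModel",
  representation(sources = "data.frame", collimators = "data.frame",
                 focus = "numeric", sfd = "numeric"),
  validity = function(object) {
    if (nrow(object@sources) != 192L) return("exactly 192 sources required")
    of16 <- object@collimators$outputFactor[object@collimators$size == 16]
    if (length(of16) != 1L || abs(of16 - 1) > 1e-12)
      return("output factor of the 16 mm collimator must be 1")
    d <- sqrt(rowSums(sweep(as.matrix(object@sources[, c("x", "y", "z")]),
                            2, object@focus)^2))
    if (any(abs(d - object@sfd) > 1e-6))
      return("all sources must lie at the source-focus distance")
    TRUE
  })

#' A single focal irradiation (shot)
#' @slot center Leksell mm point.
#' @slot sectors 8 states from `"4"`, `"8"`, `"16"`, `"blocked"`.
#' @slot weight relative duration weight, >= 0.
#' @export
setClass("Shot",
  representation(center = "numeric", sectors = "character",
                 weight = "numeric"),
  prototype(weight = 1),
  validity = function(object) {
    if (length(object@sectors) != 8L) return("8 sector states required")
    if (!all(object@sectors %in% c("4", "8", "16", "blocked")))
      return("sector states must be 4, 8, 16 or blocked")
    if (object@weight < 0) return("weight must be >= 0")
    if (object@weight > 0 && all(object@sectors == "blocked"))
      return("at least one unblocked sector required")
    TRUE
  })

#' Treatment plan
#' @slot shots list of [Shot-class].
#' @slot prescriptionDose Gy.
#' @slot prescriptionIsodose percent of maximum (0, 100].
#' @slot bot beam-on time, minutes (NA until normalized).
#' @slot refRate decay-corrected reference dose rate, Gy/min.
#' @slot refDate reference date of `refRate`.
#' @export
setClass("Plan",
  representation(shots = "list", prescriptionDose = "numeric",
                 prescriptionIsodose = "numeric", bot = "numeric",
                 refRate = "numeric", refDate = "Date"),
  prototype(bot = NA_real_),
  validity = function(object) {
    if (object@prescriptionIsodose <= 0 || object@prescriptionIsodose > 100)
      return("prescription isodose must be in (0, 100]")
    if (!is.na(object@bot) && object@bot <= 0)
      return("BOT must be positive once normalized")
    if (!length(object@shots)) return("plan needs at least one shot")
    TRUE
  })

#' Ionization-chamber measurement record
#'
#' The corrected-charge dose chain: absorbed dose to water
#' D = M kTP kPol kIon NDw KQ KQmsr, with the machine-specific reference
#' field correction defaulting to 1.0037.
#' @slot M mean corrected charge, nC.
#' @slot kTP,kPol,kIon influence-quantity corrections.
#' @slot NDw calibration coefficient, Gy/nC.
#' @slot kQ beam-quality correction.
#' @slot kQmsr machine-specific reference field correction.
#' @export
setClass("ChamberMeasurement",
  representation(M = "numeric", kTP = "numeric", kPol = "numeric",
                 kIon = "numeric", NDw = "numeric", kQ = "numeric",
                 kQmsr = "numeric"),
  prototype(kTP = 1, kPol = 1, kIon = 1, kQ = 1, kQmsr = 1.0037),
  validity = function(object) {
    vals <- c(object@M, object@kTP, object@kPol, object@kIon, object@NDw,
              object@kQ, object@kQmsr)
    if (any(vals <= 0)) return("all factors must be positive")
    TRUE
  })

#' Sector sampling distribution for the stochastic engine
#'
#' One row per active (shot, sector) pair: active time t, phase-space
#' particle count N, probability p = t N / sum(t N).
#' @slot table data.frame: shot, sector, collimator, t, N, p.
#' @export
setClass("SectorSampling",
  representation(table = "data.frame"),
  validity = function(object) {
    p <- object@table$p
    if (any(p < 0)) return("probabilities must be non-negative")
    if (abs(sum(p) - 1) > 1e-12) return("probabilities must sum to 1")
    TRUE
  })

#' Dose-to-medium correction factor table
#' @slot table data.frame: medium, field (mm), kmed.
#' @export
setClass("KmedTable",
  representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    if (any(tb$kmed <= 0)) return("K_med must be positive")
    w <- tb$kmed[tb$medium == "water"]
    if (length(w) && any(w != 1)) return("water entries must equal 1 exactly")
    TRUE
  })

#' 2D film dose map
#'
#' Pixels on a regular raster in the film frame; the film frame is embedded
#' in the stereotactic frame through `frameOrigin` and the in-plane unit
#' axes `ex`, `ey` (world of pixel (u, v) mm = frameOrigin + u ex + v ey).
#'
#' @slot pixels dose matrix, dim (nu, nv), u fastest.
#' @slot pitch mm per pixel (default 0.169).
#' @slot offset film-frame mm of pixel `[1,1]` centre.
#' @slot frameOrigin,ex,ey film-plane embedding in world mm.
#' @slot medium reporting medium flag, `"water"` or `"medium"`.
#' @slot holes n x 2 film-frame mm positions of punched fiducial holes.
#' @export
setClass("FilmImage",
  representation(pixels = "matrix", pitch = "numeric", offset = "numeric",
                 frameOrigin = "numeric", ex = "numeric", ey = "numeric",
                 medium = "character", holes = "matrix"),
  prototype(medium = "water", holes = matrix(numeric(0), 0, 2)),
  validity = function(object) {
    if (object@pitch <= 0) return("pitch must be positive")
    if (!object@medium %in% c("water", "medium"))
      return("medium must be 'water' or 'medium'")
    if (abs(sum(object@ex * object@ey)) > 1e-9)
      return("film axes must be orthogonal")
    TRUE
  })

#' Rigid transform (rotation + translation, no scale)
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation length-3 mm vector.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      return("rotation determinant must be +1 (no reflection)")
    TRUE
  })

#' Gamma-index acceptance criteria
#' @slot dd dose-difference criterion, percent (default 3, local).
#' @slot dta distance-to-agreement, mm (default 1).
#' @slot cutoff dose cut-off, Gy (default 1).
#' @slot step resampling step for the searched distribution, mm (default 0.1).
#' @slot searchRadius spatial search cap, mm (default 3 x DTA; Inf = uncapped).
#' @slot normalization `"local"` or `"global"`.
#' @slot resample which distribution is resampled for the search:
#'   `"evaluated"` (default), `"reference"` or `"both"`.
#' @export
setClass("GammaCriteria",
  representation(dd = "numeric", dta = "numeric", cutoff = "numeric",
                 step = "numeric", searchRadius = "numeric",
                 normalization = "character", resample = "character"),
  prototype(dd = 3, dta = 1, cutoff = 1, step = 0.1, searchRadius = 3,
            normalization = "local", resample = "evaluated"),
  validity = function(object) {
    if (any(c(object@dd, object@dta, object@cutoff, object@step) <= 0))
      return("criteria must be positive")
    if (object@step > object@dta) return("resample step must be <= DTA")
    if (!object@normalization %in% c("local", "global"))
      return("normalization must be 'local' or 'global'")
    if (!object@resample %in% c("evaluated", "reference", "both"))
      return("resample must be 'evaluated', 'reference' or 'both'")
    TRUE
  })

#' Gamma-index result
#' @slot gamma per-reference-point gamma values (NA where not evaluated).
#' @slot mask logical, which reference points entered the analysis.
#' @slot rate passing rate, percent of evaluated points with gamma <= 1.
#' @slot criteria the [GammaCriteria-class] used.
#' @export
setClass("GammaResult",
  representation(gamma = "array", mask = "array", rate = "numeric",
                 criteria = "GammaCriteria"),
  validity = function(object) {
    if (any(object@gamma < 0, na.rm = TRUE)) return("gamma must be >= 0")
    if (object@rate < 0 || object@rate > 100)
      return("passing rate must be in [0, 100]")
    TRUE
  })

#' GUM-style uncertainty budget
#' @slot label budget name.
#' @slot components data.frame: source, value (% at k = 1), type ("A"/"B").
#' @slot combined quadrature sum of the components, percent.
#' @export
setClass("UncertaintyBudget",
  representation(label = "character", components = "data.frame",
                 combined = "numeric"),
  validity = function(object) {
    if (any(object@components$value < 0))
      return("component values must be >= 0")
    if (abs(object@combined - sqrt(sum(object@components$value^2))) > 1e-9)
      return("combined must be the quadrature sum of the components")
    TRUE
  })

#' End-to-end verification report
#' @slot rates data.frame of gamma passing rates (reference source x
#'   air-mask handling).
#' @slot kmed named list of applied plan-average factors.
#' @slot budgets list of [UncertaintyBudget-class].
#' @slot seed integer seed of the run.
#' @slot config the configuration list used.
#' @slot log character vector of per-stage log lines.
#' @export
setClass("VerificationReport",
  representation(rates = "data.frame", kmed = "list", budgets = "list",
                 seed = "numeric", config = "list", log = "character"))
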