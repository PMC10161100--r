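#' Default source/sector/collimator model of the radiosurgery unit
#'
#' 192 cobalt sources in 8 sectors of 24, placed on 5 latitude rings of a
#' cone (4 + 5 + 5 + 5 + 5 sources per sector per ring) at the source-focus
#' distance, all aimed at the focus (100, 100, 100). Ring polar angles and
#' the source-focus distance are configurable; none of the package's
#' normalization or ratio results depend on them. Collimator parameters:
#' nominal field radius at the focus, relative output factor (16 mm = 1),
#' effective attenuation coefficient mu (cobalt-60 narrow-beam water value
#' 0.063 cm2/g), penumbra sigma, and the scatter-kernel amplitude/range of
#' the deterministic engine.
#'
#' @param sfd source-focus distance, mm.
#' @param ringAngles polar angles of the 5 rings, degrees from +z.
#' @param mu effective attenuation coefficient, cm2/g.
#' @return a [MachineModel-class].
#' @examples
#' mach <- defaultMachine()
#' nrow(mach@sources)
#' @export
defaultMachine <- function(sfd = 400, ringAngles = c(30, 40, 50, 60, 70),
                           mu = 0.063) {
  perRing <- c(4, 5, 5, 5, 5)
  focus <- c(100, 100, 100)
  rows <- list()
  for (sec in 1:8) {
    phi0 <- (sec - 1) * 45
    for (r in seq_along(ringAngles)) {
      nphi <- perRing[r]
      phis <- phi0 + (seq_len(nphi) - 0.5) * 45 / nphi
      th <- ringAngles[r] * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        sector = sec,
        x = focus[1] + sfd * sin(th) * cos(phis * pi / 180),
        y = focus[2] + sfd * sin(th) * sin(phis * pi / 180),
        z = focus[3] + sfd * cos(th))
    }
  }
  src <- do.call(rbind, rows)
  src <- src[order(src$sector), ]
  rownames(src) <- NULL
  col <- data.frame(
    size = c(4, 8, 16),
    fieldRadius = c(2, 4, 8),
    outputFactor = c(0.814, 0.900, 1.000),
    mu = mu,
    sigma = c(0.7, 0.8, 1.0),
    scatterAmp = c(0.06, 0.08, 0.10),
    scatterRange = c(8, 9, 10))
  new("MachineModel", sources = src, collimators = col, focus = focus,
      sfd = sfd)
}

#' Cobalt-60 half-life, years
#' @export
CO60_HALF_LIFE_Y <- 5.2711

#' Decay-correct a cobalt-60 reference dose rate
#'
#' @param rate0 reference dose rate, Gy/min, measured at `date0`.
#' @param date0,date calibration and plan dates (`Date` or coercible).
#' @return the rate at `date`, Gy/min.
#' @examples
#' decayCorrectedRate(3.215, as.Date("2021-01-01"), as.Date("2022-01-01"))
#' @export
decayCorrectedRate <- function(rate0, date0, date) {
  date0 <- as.Date(date0); date <- as.Date(date)
  if (date < date0) stop("plan date precedes the calibration date")
  dt_y <- as.numeric(date - date0) / 365.25
  rate0 * 2^(-dt_y / CO60_HALF_LIFE_Y)
}

#' Absorbed dose to water from a chamber measurement
#'
#' The small-field dosimetry chain:
#' D = M kTP kPol kIon NDw KQ KQmsr, with the machine-specific reference
#' field correction KQmsr defaulting to 1.0037.
#'
#' @param m a [ChamberMeasurement-class].
#' @return absorbed dose to water, Gy.
#' @examples
#' chamberDose(new("ChamberMeasurement", M = 1, NDw = 1))
#' @export
chamberDose <- function(m) {
  validObject(m)
  m@M * m@kTP * m@kPol * m@kIon * m@NDw * m@kQ * m@kQmsr
}

#' Create a shot
#' @param center shot centre, Leksell mm.
#' @param sectors 8 sector states (`"4"`, `"8"`, `"16"`, `"blocked"`), or a
#'   single state recycled to all 8 sectors.
#' @param weight relative duration weight.
#' @return a [Shot-class].
#' @export
shot <- function(center = c(100, 100, 100), sectors = "16", weight = 1) {
  if (length(sectors) == 1L) sectors <- rep(sectors, 8)
  new("Shot", center = as.numeric(center), sectors = as.character(sectors),
      weight = weight)
}

#' Reference single-shot plan
#'
#' One 16 mm shot at the unit centre point, 4 Gy prescribed at the 50%
#' isodose surface.
#' @param prescriptionDose Gy.
#' @param prescriptionIsodose percent of maximum.
#' @param refRate decay-corrected reference dose rate, Gy/min.
#' @param center shot centre mm.
#' @return a [Plan-class].
#' @export
singleShotPlan <- function(prescriptionDose = 4, prescriptionIsodose = 50,
                           refRate = 3.215, center = c(100, 100, 100)) {
  new("Plan", shots = list(shot(center, "16")),
      prescriptionDose = prescriptionDose,
      prescriptionIsodose = prescriptionIsodose,
      refRate = refRate, refDate = as.Date("2022-01-01"))
}

#' Synthetic multi-shot plan
#'
#' Seven shots mimicking the field-size mix of a clinical composite plan:
#' four 4 mm shots, one 8 mm shot and two composite shots mixing the 4, 8
#' and 16 mm channels across sectors, spread around the core region. Shot
#' weights default to equal.
#'
#' @inheritParams singleShotPlan
#' @return a [Plan-class].
#' @export
multiShotPlan <- function(prescriptionDose = 4, prescriptionIsodose = 50,
                          refRate = 3.215) {
  comp <- rep(c("4", "8", "16", "8"), 2)
  shots <- list(
    shot(c(96, 96, 100), "4"), shot(c(104, 96, 100), "4"),
    shot(c(96, 104, 100), "4"), shot(c(104, 104, 100), "4"),
    shot(c(100, 100, 100), "8"),
    shot(c(100, 96, 100), comp), shot(c(100, 104, 100), comp))
  new("Plan", shots = shots, prescriptionDose = prescriptionDose,
      prescriptionIsodose = prescriptionIsodose,
      refRate = refRate, refDate = as.Date("2022-01-01"))
}

#' Sector sampling distribution of a plan
#'
#' Each active (shot, sector) pair is one sampling category with active time
#' t = shot duration weight, probability p = t N / sum(t N) over all active
#' pairs, where N is the phase-space particle count of the pair's
#' collimator. Blocked sectors get t = 0 and are dropped.
#'
#' @param plan a [Plan-class].
#' @param phspCounts named numeric: phase-space particle count per
#'   collimator (`"4"`, `"8"`, `"16"`); equal counts by default.
#' @return a [SectorSampling-class].
#' @examples
#' sectorProbabilities(singleShotPlan())
#' @export
sectorProbabilities <- function(plan,
                                phspCounts = c("4" = 1, "8" = 1, "16" = 1)) {
  rows <- list()
  for (s in seq_along(plan@shots)) {
    sh <- plan@shots[[s]]
    for (sec in 1:8) {
      st <- sh@sectors[sec]
      if (st == "blocked") next
      N <- phspCounts[[st]]
      if (is.null(N) || N <= 0)
        stop("phase-space count missing or non-positive for collimator ", st)
      rows[[length(rows) + 1L]] <- data.frame(
        shot = s, sector = sec, collimator = as.numeric(st),
        t = sh@weight, N = N)
    }
  }
  tb <- do.call(rbind, rows)
  if (is.null(tb) || sum(tb$t) == 0)
    stop("all sector active times are zero")
  tb$p <- tb$t * tb$N / sum(tb$t * tb$N)
  new("SectorSampling", table = tb)
}

#' Normalize a relative dose grid to the prescription
#'
#' Chooses the scale so that the prescription dose sits at the prescription
#' isodose of the scaled maximum (max dose = prescription / isodose
#' fraction), and derives the beam-on time from the reference dose rate:
#' the engine's relative dose `refRel` at the calibration point corresponds
#' to `plan@refRate` Gy/min.
#'
#' @param relDose [VoxelGrid-class] of relative (unitless) dose.
#' @param plan a [Plan-class].
#' @param refRel relative dose value corresponding to the reference rate
#'   (engine value at the UCP of the reference water sphere).
#' @return list with `scale` (Gy per relative unit) and `bot` (minutes).
#' @export
normalizePrescription <- function(relDose, plan, refRel) {
  relMax <- max(relDose@voxels)
  if (relMax <= 0) stop("relative dose grid has no positive maximum")
  dmax <- plan@prescriptionDose / (plan@prescriptionIsodose / 100)
  scale <- dmax / relMax
  rateMax <- plan@refRate * relMax / refRel
  list(scale = scale, bot = dmax / rateMax)
}
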