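#' Default HU calibration curve
#'
#' A packaged two-segment curve through (-1000, 0.001), (0, 1.0),
#' (1600, 1.9), approximating a typical 120 kVp scanner, with a matching
#' HU to mass-density branch obtained by pushing the electron densities
#' through [etaToRho()]. Scanner-specific curves can be loaded with
#' [readCalibrationCurve()].
#'
#' @return a [CalibrationCurve-class].
#' @export
defaultCurve <- function() {
  hu <- c(-1000, 0, 1600)
  eta <- c(0.001, 1.0, 1.9)
  new("CalibrationCurve", hu = hu, eta = eta, huRho = hu,
      rho = etaToRho(eta))
}

#' Map CT numbers to relative electron density
#'
#' Piecewise-linear interpolation of the scanner calibration curve on a
#' voxel-by-voxel basis; HU outside the breakpoint range clamp to the end
#' values (preventing noise from producing negative densities).
#'
#' @param hu HU value, vector or [VoxelGrid-class].
#' @param curve a [CalibrationCurve-class].
#' @return relative electron density, same shape as `hu`.
#' @examples
#' curve <- defaultCurve()
#' huToEta(c(-1000, 0, 800), curve)
#' @export
huToEta <- function(hu, curve) {
  validObject(curve)
  if (is(hu, "VoxelGrid")) {
    return(voxelGrid(array(huToEta(as.vector(hu@voxels), curve),
                           dim(hu@voxels)),
                     spacing = hu@spacing, origin = hu@origin))
  }
  approx(curve@hu, curve@eta, xout = hu, rule = 2, ties = "ordered")$y
}

.huToRhoMC <- function(hu, curve) {
  if (!length(curve@huRho))
    stop("calibration curve carries no HU -> mass-density branch")
  approx(curve@huRho, curve@rho, xout = hu, rule = 2, ties = "ordered")$y
}

#' Convert relative electron density to mass density
#'
#' The continuous piecewise conversion used by the convolution pathway:
#' \deqn{\rho = \eta \quad (\eta \le 1), \qquad
#'       \rho = (\eta - 0.15)/0.85 \quad (\eta > 1).}
#' The branch for \eqn{\eta > 1} is the unique affine form continuous at
#' \eqn{\eta = 1} that reproduces the tabled solid-water (1.013 -> 1.015)
#' and bone (1.605 -> 1.7118) conversions.
#'
#' @param eta relative electron density (>= 0), vector or
#'   [VoxelGrid-class].
#' @return mass density in g/cm3, same shape as `eta`.
#' @examples
#' etaToRho(c(0.993, 1.013, 1.605))
#' @export
etaToRho <- function(eta) {
  if (is(eta, "VoxelGrid")) {
    return(voxelGrid(array(etaToRho(as.vector(eta@voxels)), dim(eta@voxels)),
                     spacing = eta@spacing, origin = eta@origin))
  }
  if (any(eta < 0)) stop("relative electron density must be >= 0")
  ifelse(eta <= 1, eta, (eta - 0.15) / 0.85)
}

#' Assign a tissue-composition bin from mass density
#'
#' Returns the index of the packaged density-interval bin (see
#' [compositionBins()]) containing each density; extreme bins are
#' open-ended.
#'
#' @param rho mass density g/cm3 (>= 0).
#' @return integer bin index (1 = air ... 5 = bone).
#' @examples
#' rhoToComposition(c(0.0012, 1.0, 1.72))
#' @export
rhoToComposition <- function(rho) {
  if (any(rho < 0)) stop("mass density must be >= 0")
  findInterval(rho, compositionBins()$rhoLow)
}

#' Build per-voxel density maps from a CT grid
#'
#' Maps HU to relative electron density through the calibration curve, then
#' to mass density either via the continuous electron-density conversion
#' (`pathway = "lgp"`, the convolution route) or via the curve's own
#' HU to mass-density branch (`pathway = "mc"`). The composition-bin grid
#' indexes the packaged tissue bins.
#'
#' @param ct a [VoxelGrid-class] of HU.
#' @param curve a [CalibrationCurve-class].
#' @param pathway `"lgp"` or `"mc"`.
#' @return a [DensityMaps-class].
#' @export
buildDensityMaps <- function(ct, curve = defaultCurve(), pathway = "lgp") {
  pathway <- match.arg(pathway, c("lgp", "mc"))
  hu <- as.vector(ct@voxels)
  eta <- huToEta(hu, curve)
  rho <- if (pathway == "lgp") etaToRho(eta) else .huToRhoMC(hu, curve)
  mk <- function(v) voxelGrid(array(v, dim(ct@voxels)),
                              spacing = ct@spacing, origin = ct@origin)
  new("DensityMaps", eta = mk(eta), rho = mk(rho),
      bin = mk(rhoToComposition(rho)))
}

#' Read / write a calibration curve as CSV
#'
#' CSV columns: `hu`, `eta` and optionally `rho` (the HU to mass-density
#' branch used on the Monte Carlo pathway).
#' @param path file path.
#' @param curve a [CalibrationCurve-class].
#' @return `readCalibrationCurve` returns a [CalibrationCurve-class].
#' @export
readCalibrationCurve <- function(path) {
  df <- read.csv(path)
  rho <- if ("rho" %in% names(df)) df$rho else numeric(0)
  new("CalibrationCurve", hu = df$hu, eta = df$eta,
      huRho = if (length(rho)) df$hu else numeric(0), rho = rho)
}

#' @rdname readCalibrationCurve
#' @export
writeCalibrationCurve <- function(curve, path) {
  df <- data.frame(hu = curve@hu, eta = curve@eta)
  if (length(curve@rho) == length(curve@hu)) df$rho <- curve@rho
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
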