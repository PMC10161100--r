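#' Default material table of the inhomogeneous phantom
#'
#' Densities follow the measured values for the phantom constituents: RW3
#' (eta 0.993), the solid-water sphere material (eta 1.013), the 3D-printed
#' bone-mimicking material (rho 1.720, eta 1.605), air, water and the metal
#' fiducial pins (flagged metal: outside any CT calibration curve, imaged as
#' a fixed HU plateau). Elemental compositions are mass fractions used only
#' on the Monte Carlo pathway.
#'
#' @return a [MaterialTable-class].
#' @examples
#' materialTable()
#' @export
materialTable <- function() {
  tb <- data.frame(
    material = c("water", "lgk_sw", "rw3", "bone", "air", "metal"),
    rho = c(1.000, 1.038, 1.014, 1.720, 0.0012, 7.9),
    eta = c(1.000, 1.013, 0.993, 1.605, 0.0011, 6.6),
    metal = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  comp <- list(
    water = c(H = 0.112, O = 0.888),
    lgk_sw = c(H = 0.081, C = 0.672, N = 0.024, O = 0.199, Cl = 0.001,
               Ca = 0.023),
    rw3 = c(H = 0.076, C = 0.904, O = 0.008, Ti = 0.012),
    bone = c(H = 0.034, C = 0.155, N = 0.042, O = 0.435, P = 0.103,
             Ca = 0.225, Na = 0.003, Mg = 0.002, S = 0.001),
    air = c(N = 0.755, O = 0.232, Ar = 0.013),
    metal = c(Fe = 0.70, Cr = 0.19, Ni = 0.11))
  new("MaterialTable", table = tb, composition = comp)
}

#' Look up a material property
#' @param materials a [MaterialTable-class].
#' @param material material name.
#' @param what `"rho"`, `"eta"` or `"metal"`.
#' @export
materialProperty <- function(materials, material, what = "eta") {
  tb <- materials@table
  i <- match(material, tb$material)
  if (anyNA(i)) stop("unknown material: ",
                     paste(material[is.na(i)], collapse = ", "))
  tb[[what]][i]
}

#' Packaged tissue-composition bins
#'
#' A 5-bin simplification of density-interval based tissue segmentation
#' (air / lung / adipose / soft tissue / bone ramp): each bin carries a
#' density interval and an elemental mass-fraction composition. Extreme
#' bins are open-ended.
#'
#' @return data.frame with columns bin, name, rhoLow, rhoHigh and a
#'   `composition` list column of mass fractions (each summing to 1).
#' @export
compositionBins <- function() {
  df <- data.frame(
    bin = 1:5,
    name = c("air", "lung", "adipose", "soft", "bone"),
    rhoLow = c(0, 0.05, 0.8, 0.95, 1.2),
    rhoHigh = c(0.05, 0.8, 0.95, 1.2, Inf),
    stringsAsFactors = FALSE)
  df$composition <- list(
    c(N = 0.755, O = 0.232, Ar = 0.013),
    c(H = 0.103, C = 0.105, N = 0.031, O = 0.749, Na = 0.002, P = 0.002,
      S = 0.003, Cl = 0.003, K = 0.002),
    c(H = 0.114, C = 0.598, N = 0.007, O = 0.278, Na = 0.001, S = 0.001,
      Cl = 0.001),
    c(H = 0.105, C = 0.134, N = 0.030, O = 0.723, Na = 0.002, P = 0.002,
      S = 0.002, Cl = 0.001, K = 0.001),
    c(H = 0.056, C = 0.235, N = 0.050, O = 0.434, P = 0.072, Ca = 0.146,
      Na = 0.001, Mg = 0.002, S = 0.003, Cl = 0.001))
  df
}
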