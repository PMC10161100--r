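#' Synthesize a CT of the labelled phantom
#'
#' Emulates the CT acquisition: each voxel receives the HU at which the
#' calibration curve maps back to its material's relative electron density
#' (inverse piecewise-linear interpolation), plus zero-mean Gaussian noise.
#' Metal materials sit outside any clinical calibration curve and are imaged
#' at a fixed saturation plateau, mirroring clinical metal behaviour.
#'
#' @param labels a [LabelGrid-class].
#' @param materials a [MaterialTable-class].
#' @param curve a [CalibrationCurve-class].
#' @param noiseSd HU noise standard deviation (0 = noiseless).
#' @param seed integer; the result is bit-reproducible given the seed.
#' @param metalHU plateau HU for metal materials (default 3000).
#' @return a [VoxelGrid-class] of HU values.
#' @examples
#' labels <- buildPhantom(phantomSpec(spacing = 4))
#' ct <- synthesizeCT(labels, materialTable(), defaultCurve(), noiseSd = 0)
#' @export
synthesizeCT <- function(labels, materials, curve = defaultCurve(),
                         noiseSd = 0, seed = 1L, metalHU = 3000) {
  tb <- materials@table
  i <- match(labels@materials, tb$material)
  if (anyNA(i)) stop("label grid references unknown materials: ",
                     paste(labels@materials[is.na(i)], collapse = ", "))
  eta <- tb$eta[i]
  metal <- tb$metal[i]
  bad <- !metal & (eta < min(curve@eta) | eta > max(curve@eta))
  if (any(bad))
    stop("relative electron density outside the calibration curve for: ",
         paste(labels@materials[bad], collapse = ", "))
  huOf <- ifelse(metal, metalHU,
                 approx(curve@eta, curve@hu, xout = eta, ties = "ordered")$y)
  hu <- huOf[labels@voxels]
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    hu <- hu + rnorm(length(hu), 0, noiseSd)
  }
  voxelGrid(array(hu, dim(labels@voxels)), spacing = labels@spacing,
            origin = labels@origin)
}
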