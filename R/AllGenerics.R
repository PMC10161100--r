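#' @rdname VoxelGrid-class
#' @param object,x a grid-like object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname DoseGrid-class
#' @param x a [DoseGrid-class] or [FilmImage-class].
#' @export
setGeneric("reportingMedium", function(x) standardGeneric("reportingMedium"))

#' @rdname GammaResult-class
#' @param x a [GammaResult-class].
#' @export
setGeneric("passRate", function(x) standardGeneric("passRate"))

#' @rdname GammaResult-class
#' @export
setGeneric("gammaValues", function(x) standardGeneric("gammaValues"))

#' @export
#' @rdname VoxelGrid-class
setMethod("voxels", "VoxelGrid", function(x) x@voxels)

#' @export
#' @rdname VoxelGrid-class
setMethod("spacing", "VoxelGrid", function(x) x@spacing)

#' @export
#' @rdname VoxelGrid-class
setMethod("origin", "VoxelGrid", function(x) x@origin)

#' @export
#' @rdname DoseGrid-class
setMethod("reportingMedium", "DoseGrid", function(x) x@medium)

#' @export
#' @rdname DoseGrid-class
setMethod("reportingMedium", "FilmImage", function(x) x@medium)

#' @export
#' @rdname GammaResult-class
setMethod("passRate", "GammaResult", function(x) x@rate)

#' @export
#' @rdname GammaResult-class
setMethod("gammaValues", "GammaResult", function(x) x@gamma)

#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@voxels))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "LabelGrid", function(object) {
  callNextMethod()
  tb <- table(factor(object@voxels, levels = seq_along(object@materials),
                     labels = object@materials))
  cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
})

setMethod("show", "DoseGrid", function(object) {
  callNextMethod()
  cat(sprintf("  dose-to-%s%s\n", object@medium,
              if (is.null(object@uncertainty)) "" else
                ", with batch uncertainties"))
})

setMethod("show", "FilmImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "FilmImage: %d x %d px at %.3f mm/px, dose-to-%s, %d fiducial holes\n",
    d[1], d[2], object@pitch, object@medium, nrow(object@holes)))
})

setMethod("show", "Plan", function(object) {
  cat(sprintf(
    "Plan: %d shot(s), %.3g Gy at %.3g%% isodose, BOT %s min, ref rate %.4g Gy/min\n",
    length(object@shots), object@prescriptionDose,
    object@prescriptionIsodose,
    if (is.na(object@bot)) "<unset>" else sprintf("%.3g", object@bot),
    object@refRate))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf(
    "GammaResult: %.1f%% passing (%d evaluated points), %g%%/%g mm %s, cutoff %g Gy\n",
    object@rate, sum(object@mask), object@criteria@dd, object@criteria@dta,
    object@criteria@normalization, object@criteria@cutoff))
})

setMethod("show", "UncertaintyBudget", function(object) {
  cat(sprintf("UncertaintyBudget '%s': combined %.1f%% (k = 1)\n",
              object@label, object@combined))
  print(object@components, row.names = FALSE)
})
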