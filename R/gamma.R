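#' Construct gamma-index criteria
#'
#' @param dd dose-difference criterion, percent (local normalization by
#'   default).
#' @param dta distance-to-agreement, mm.
#' @param cutoff dose cut-off, Gy: reference points below it are not
#'   evaluated.
#' @param step resampling step of the searched distribution, mm.
#' @param searchRadius spatial search cap, mm (default 3 x DTA; `Inf`
#'   disables the cap).
#' @param normalization `"local"` (reference point's own dose in the
#'   denominator) or `"global"` (reference maximum).
#' @param resample which distribution is resampled to `step` for the
#'   search: `"evaluated"` (default), `"reference"` or `"both"`.
#' @return a [GammaCriteria-class].
#' @export
gammaCriteria <- function(dd = 3, dta = 1, cutoff = 1, step = 0.1,
                          searchRadius = 3 * dta, normalization = "local",
                          resample = "evaluated") {
  new("GammaCriteria", dd = dd, dta = dta, cutoff = cutoff, step = step,
      searchRadius = searchRadius, normalization = normalization,
      resample = resample)
}

# regular-raster view of a map: list(values, org, step, dims)
.asRaster <- function(map) {
  if (is(map, "FilmImage"))
    return(list(values = map@pixels, org = map@offset,
                step = rep(map@pitch, 2), dims = dim(map@pixels)))
  if (is(map, "VoxelGrid"))
    return(list(values = map@voxels, org = map@origin, step = map@spacing,
                dims = dim(map@voxels)))
  if (is.list(map) && all(c("values", "org", "step") %in% names(map))) {
    map$dims <- dim(map$values) %||% length(map$values)
    return(map)
  }
  if (is.matrix(map))
    return(list(values = map, org = c(0, 0), step = c(1, 1),
                dims = dim(map)))
  if (is.numeric(map))
    return(list(values = map, org = 0, step = 1, dims = length(map)))
  stop("unsupported map type: ", class(map)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linearly resample a map onto a finer regular raster
#'
#' Separable linear interpolation onto a raster of the given step covering
#' the same extent (1D profiles, 2D films or 3D grids).
#'
#' @param map a [FilmImage-class], [VoxelGrid-class], matrix, numeric
#'   vector, or list(values, org, step).
#' @param step target step, mm (scalar, applied to every axis).
#' @return list(values, org, step, dims).
#' @export
resampleMap <- function(map, step) {
  r <- .asRaster(map)
  nd <- length(r$dims)
  if (any(step <= 0)) stop("step must be positive")
  ext <- (r$dims - 1) * r$step
  if (any(step > ext)) stop("step larger than the map extent")
  n <- as.integer(floor(ext / step + 1e-9)) + 1L
  ax <- lapply(seq_len(nd), function(a) r$org[a] + (seq_len(n[a]) - 1) * step)
  vals <- r$values
  # interpolate axis by axis
  for (a in seq_len(nd)) {
    old <- r$org[a] + (seq_len(r$dims[a]) - 1) * r$step[a]
    pos <- (ax[[a]] - r$org[a]) / r$step[a]
    i0 <- pmin(pmax(floor(pos), 0), r$dims[a] - 2)
    f <- pos - i0
    if (nd == 1L) {
      vals <- vals[i0 + 1] * (1 - f) + vals[i0 + 2] * f
    } else {
      vals <- .sliceInterp(vals, a, i0, f)
    }
  }
  list(values = if (nd == 1L) vals else array(vals, n),
       org = r$org[seq_len(nd)], step = rep(step, nd), dims = n)
}

# linear interpolation along axis a of an array
.sliceInterp <- function(vals, a, i0, f) {
  nd <- length(dim(vals))
  idx0 <- lapply(dim(vals), seq_len)
  idx1 <- idx0
  idx0[[a]] <- i0 + 1
  idx1[[a]] <- i0 + 2
  v0 <- do.call(`[`, c(list(vals), idx0, list(drop = FALSE)))
  v1 <- do.call(`[`, c(list(vals), idx1, list(drop = FALSE)))
  shape <- rep(1, nd); shape[a] <- length(f)
  fa <- array(rep(f, each = prod(dim(vals)[seq_len(a - 1)])), dim(v0))
  v0 * (1 - fa) + v1 * fa
}

#' Gamma-index map between a reference and an evaluated distribution
#'
#' At each reference point r above the cut-off and inside the inclusion
#' mask, \deqn{\gamma(r) = \min_e \sqrt{|r-e|^2/DTA^2 +
#' (D_e - D_r)^2/(f D_r)^2}} with f = DD/100 (local normalization uses the
#' reference point's own dose in the denominator). The minimum runs over
#' the evaluated distribution resampled to the criteria's step (see the
#' `resample` criterion for the reference/evaluated/both convention); the
#' optimized expanding-shell search is exact (equals exhaustive search).
#' The passing rate is the percentage of evaluated reference points with
#' gamma <= 1.
#'
#' @param reference,evaluated maps sharing a frame (post-registration):
#'   [FilmImage-class], matrix, numeric profile, or list(values, org,
#'   step).
#' @param criteria a [GammaCriteria-class].
#' @param includeMask optional logical mask of reference points eligible
#'   for evaluation.
#' @return a [GammaResult-class].
#' @export
gammaMap <- function(reference, evaluated, criteria = gammaCriteria(),
                     includeMask = NULL) {
  validObject(criteria)
  ref <- .asRaster(reference)
  ev <- .asRaster(evaluated)
  if (length(ref$dims) != length(ev$dims))
    stop("reference and evaluated maps have mismatched frames")
  if (criteria@resample %in% c("reference", "both")) {
    rr <- resampleMap(ref, criteria@step)
    if (!is.null(includeMask)) {
      mgrid <- .asRaster(ref)
      mgrid$values <- array(as.numeric(includeMask), dim = ref$dims)
      includeMask <- resampleMap(mgrid, criteria@step)$values >= 0.5
    }
    ref <- rr
  }
  evFine <- if (criteria@resample %in% c("evaluated", "both"))
    resampleMap(ev, criteria@step) else ev
  nd <- length(ref$dims)
  ax <- lapply(seq_len(nd), function(a)
    ref$org[a] + (seq_len(ref$dims[a]) - 1) * ref$step[a])
  coords <- as.matrix(do.call(expand.grid, ax))
  refd <- as.vector(ref$values)
  mask <- refd > criteria@cutoff
  if (!is.null(includeMask)) mask <- mask & as.vector(includeMask)
  if (!any(mask)) stop("empty evaluation set: no points above the cut-off")
  g <- rep(NA_real_, length(refd))
  g[mask] <- cpp_gamma_search(
    coords[mask, , drop = FALSE], refd[mask],
    as.numeric(evFine$values), as.integer(evFine$dims),
    as.numeric(evFine$org), as.numeric(evFine$step),
    criteria@dd / 100, criteria@dta, criteria@searchRadius,
    criteria@normalization == "local", max(refd))
  res <- new("GammaResult",
             gamma = array(g, if (nd >= 2) ref$dims else length(g)),
             mask = array(mask, if (nd >= 2) ref$dims else length(g)),
             rate = 100 * mean(g[mask] <= 1), criteria = criteria)
  res
}

#' 1D gamma profile
#'
#' Specialization of [gammaMap()] to 1D dose profiles.
#' @param refProfile,evalProfile numeric vectors or list(values, org,
#'   step).
#' @param criteria a [GammaCriteria-class].
#' @return per-point gamma values (NA below the cut-off).
#' @export
gammaProfile1d <- function(refProfile, evalProfile,
                           criteria = gammaCriteria()) {
  as.vector(gammaMap(refProfile, evalProfile, criteria)@gamma)
}

#' Passing rate under inclusion/exclusion masks
#'
#' Recomputes the passing rate of a [GammaResult-class] over the points
#' above the cut-off that fall inside all `include` masks and outside all
#' `exclude` masks (e.g. with and without the air-cavity mask).
#'
#' @param result a [GammaResult-class].
#' @param include,exclude logical masks (or lists of masks) on the
#'   reference raster.
#' @return passing rate, percent.
#' @export
passingRate <- function(result, include = NULL, exclude = NULL) {
  m <- result@mask
  addMask <- function(m, x, keep) {
    if (is.null(x)) return(m)
    if (!is.list(x)) x <- list(x)
    for (mm in x) m <- m & (if (keep) mm else !mm)
    m
  }
  m <- addMask(m, include, TRUE)
  m <- addMask(m, exclude, FALSE)
  if (!any(m)) stop("empty evaluation set after masking")
  100 * mean(result@gamma[m] <= 1)
}
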