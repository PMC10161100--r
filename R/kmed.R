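#' K_med from the two Monte Carlo dose ratios
#'
#' The dose-to-medium correction factor of a water-calibrated film reading
#' inside a medium is the product of (dose to medium / dose to film) at the
#' treatment geometry and (dose to film / dose to water) at the calibration
#' geometry.
#'
#' @param dMedOverDFilmLGK unitless ratio at the treatment geometry.
#' @param dFilmOverDwCal unitless ratio at the calibration geometry.
#' @return K_med.
#' @examples
#' kmedFromRatios(1, 1)          # water identity
#' @export
kmedFromRatios <- function(dMedOverDFilmLGK, dFilmOverDwCal) {
  if (any(c(dMedOverDFilmLGK, dFilmOverDwCal) <= 0))
    stop("dose ratios must be positive")
  dMedOverDFilmLGK * dFilmOverDwCal
}

#' Default dose-to-medium correction table
#'
#' Packaged field-size-resolved factors for the bone and air inhomogeneity
#' media (bone: 0.941/0.946/0.946 and air: 0.745/0.748/0.749 for the
#' 16/8/4 mm fields), as determined by full Monte Carlo transport; the
#' package consumes them as data (no electron transport is performed here).
#' Water rows are identically 1. Users may supply their own table, e.g.
#' via [readKmedTable()].
#'
#' @return a [KmedTable-class].
#' @export
defaultKmedTable <- function() {
  tb <- data.frame(
    medium = rep(c("bone", "air", "water"), each = 3),
    field = rep(c(16, 8, 4), 3),
    kmed = c(0.941, 0.946, 0.946, 0.745, 0.748, 0.749, 1, 1, 1))
  new("KmedTable", table = tb)
}

#' Plan-average K_med over the field sizes used
#'
#' Unweighted arithmetic mean of the per-field-size factors over the
#' distinct field sizes used by a plan (a beam-on-time weighted mean is
#' available behind the `weights` argument).
#'
#' @param table a [KmedTable-class].
#' @param medium `"bone"` or `"air"` (or any medium in the table).
#' @param fieldSizes field sizes used by the plan, mm.
#' @param weights optional weights (same length as the distinct field
#'   sizes) for a time-weighted mean.
#' @return averaged K_med.
#' @examples
#' planAverageKmed(defaultKmedTable(), "bone", c(4, 8, 16))  # 0.944
#' @export
planAverageKmed <- function(table, medium, fieldSizes, weights = NULL) {
  fs <- sort(unique(as.numeric(fieldSizes)))
  tb <- table@table
  k <- vapply(fs, function(f) {
    i <- which(tb$medium == medium & tb$field == f)
    if (!length(i))
      stop(sprintf("no K_med entry for (%s, %g mm)", medium, f))
    tb$kmed[i[1]]
  }, numeric(1))
  if (is.null(weights)) mean(k) else sum(k * weights) / sum(weights)
}

#' Field sizes used by a plan
#' @param plan a [Plan-class].
#' @return sorted distinct collimator sizes, mm.
#' @export
planFieldSizes <- function(plan) {
  st <- unlist(lapply(plan@shots, function(s) s@sectors))
  sort(unique(as.numeric(st[st != "blocked"])))
}

#' Convert a dose-to-water map to dose-to-medium
#'
#' Multiplies the pixels inside each medium mask by that medium's K_med
#' factor; water-equivalent pixels are unchanged. Applying the conversion
#' to a map already flagged dose-to-medium raises (double-conversion
#' guard).
#'
#' @param map a [FilmImage-class] or [DoseGrid-class] flagged
#'   dose-to-water.
#' @param masks named list of logical masks (same shape as the map) for
#'   the media to convert, e.g. `list(bone =, air =)`.
#' @param factors named K_med factors per medium (e.g. from
#'   [planAverageKmed()]), or a [KmedTable-class] together with
#'   `fieldSizes`.
#' @param fieldSizes plan field sizes, needed when `factors` is a table.
#' @return the converted map, flagged dose-to-medium.
#' @export
applyKmed <- function(map, masks, factors, fieldSizes = NULL) {
  if (reportingMedium(map) == "medium")
    stop("map is already dose-to-medium (double conversion)")
  if (is(factors, "KmedTable")) {
    if (is.null(fieldSizes))
      stop("fieldSizes required when factors is a KmedTable")
    factors <- vapply(names(masks), function(m)
      planAverageKmed(factors, m, fieldSizes), numeric(1))
  }
  px <- if (is(map, "FilmImage")) map@pixels else map@voxels
  for (nm in names(masks)) {
    if (is.null(factors[[nm]]))
      stop("no K_med factor for medium: ", nm)
    px[masks[[nm]]] <- px[masks[[nm]]] * factors[[nm]]
  }
  if (is(map, "FilmImage")) {
    map@pixels <- px
  } else map@voxels <- px
  map@medium <- "medium"
  map
}

#' Region masks of the phantom media on a film raster
#'
#' Resamples the phantom label grid through the registration transform onto
#' the film raster (nearest neighbour) and returns one logical mask per
#' requested medium group.
#'
#' @param labels a [LabelGrid-class].
#' @param film a [FilmImage-class] providing the raster.
#' @param t [RigidTransform-class] mapping film frame to grid frame.
#' @param groups named list mapping mask name -> material names.
#' @return named list of logical matrices.
#' @export
regionMasksOnFilm <- function(labels, film, t = identityTransform(),
                              groups = list(bone = "bone", air = "air")) {
  world <- applyTransform(t, filmPixelWorld(film))
  lab <- sampleGrid(labels, world, outside = NA, nearest = TRUE)
  mat <- labels@materials[lab]
  n <- dim(film@pixels)
  lapply(groups, function(ms) matrix(mat %in% ms, n[1], n[2]))
}

#' Read / write a K_med table as CSV (columns medium, field, kmed)
#' @param path file path.
#' @param table a [KmedTable-class].
#' @export
readKmedTable <- function(path) {
  new("KmedTable", table = read.csv(path))
}

#' @rdname readKmedTable
#' @export
writeKmedTable <- function(table, path) {
  write.csv(table@table, path, row.names = FALSE)
  invisible(path)
}
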