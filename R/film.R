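#' Film-plane specification
#'
#' Embeds the film frame in the stereotactic frame: film point (u, v) mm
#' maps to `origin + u ex + v ey`. The default is the axial plane z = 100 mm
#' through the unit centre point with film x along stereotactic x and film y
#' along stereotactic y.
#'
#' @param origin world mm of the film-frame origin.
#' @param ex,ey in-plane unit axes (orthogonal).
#' @return list(origin, ex, ey).
#' @export
filmPlane <- function(origin = c(100, 100, 100), ex = c(1, 0, 0),
                      ey = c(0, 1, 0)) {
  ex <- ex / sqrt(sum(ex^2)); ey <- ey / sqrt(sum(ey^2))
  if (abs(sum(ex * ey)) > 1e-9) stop("film axes must be orthogonal")
  list(origin = origin, ex = ex, ey = ey)
}

#' Simulate a film measurement of a 3D dose grid
#'
#' Samples the dose grid trilinearly on the (rigidly transformed) film
#' plane, multiplies each pixel by (1 + eps) with
#' eps ~ Normal(0, noiseFraction), punches circular zero-dose holes at the
#' pin lance positions and flags the result dose-to-water. When a
#' `response` is supplied (region masks plus K_med factors) the sampled
#' dose-to-medium is divided by K_med inside bone/air, emulating the
#' water-calibrated film's under-response in those media.
#'
#' @param dose a [DoseGrid-class].
#' @param plane a [filmPlane()] spec.
#' @param pitch pixel pitch, mm/px (default 0.169).
#' @param sizeMm film extent (u, v) in mm, centred on the plane origin.
#' @param trueTransform [RigidTransform-class] applied to the film-plane
#'   points before sampling (identity = nominally mounted film).
#' @param noiseFraction relative measurement noise (0 = noiseless).
#' @param pins world mm positions of the fiducial pins (n x 3); holes are
#'   punched where they lance the film plane.
#' @param holeRadius punched-hole radius, mm.
#' @param seed integer seed for the noise.
#' @param response optional list(masks = list of logical pixel matrices,
#'   factors = named K_med values) for the medium response.
#' @return a [FilmImage-class] (dose-to-water).
#' @export
simulateFilm <- function(dose, plane = filmPlane(), pitch = 0.169,
                         sizeMm = c(80, 80),
                         trueTransform = identityTransform(),
                         noiseFraction = 0, pins = NULL, holeRadius = 0.5,
                         seed = 1L, response = NULL) {
  n <- pmax(2L, as.integer(round(sizeMm / pitch)) + 1L)
  off <- -(n - 1) / 2 * pitch
  u <- off[1] + (seq_len(n[1]) - 1) * pitch
  v <- off[2] + (seq_len(n[2]) - 1) * pitch
  uv <- as.matrix(expand.grid(u = u, v = v))
  world <- matrix(plane$origin, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %o% plane$ex + uv[, 2] %o% plane$ey
  world <- applyTransform(trueTransform, world)
  inGrid <- .worldToIndex(dose, world)
  d <- dim(dose@voxels)
  if (!any(inGrid[, 1] >= 0 & inGrid[, 1] <= d[1] - 1 &
           inGrid[, 2] >= 0 & inGrid[, 2] <= d[2] - 1 &
           inGrid[, 3] >= 0 & inGrid[, 3] <= d[3] - 1))
    stop("film plane does not intersect the dose grid")
  px <- matrix(sampleGrid(dose, world), n[1], n[2])
  if (!is.null(response)) {
    for (nm in names(response$factors)) {
      m <- response$masks[[nm]]
      if (!is.null(m)) px[m] <- px[m] / response$factors[[nm]]
    }
  }
  if (noiseFraction > 0) {
    set.seed(as.integer(seed))
    px <- px * (1 + matrix(rnorm(length(px), 0, noiseFraction), n[1], n[2]))
  }
  holes <- matrix(numeric(0), 0, 2)
  if (!is.null(pins)) {
    holes <- .pinsToFilmFrame(pins, plane, trueTransform)
    for (h in seq_len(nrow(holes))) {
      du <- outer(u - holes[h, 1], rep(1, n[2]))
      dv <- outer(rep(1, n[1]), v - holes[h, 2])
      px[du^2 + dv^2 <= holeRadius^2] <- 0
    }
  }
  new("FilmImage", pixels = px, pitch = pitch, offset = off,
      frameOrigin = plane$origin, ex = plane$ex, ey = plane$ey,
      medium = "water", holes = holes)
}

# film-frame (u, v) of pins lancing the transformed film plane
.pinsToFilmFrame <- function(pins, plane, transform) {
  pins <- matrix(as.numeric(pins), ncol = 3)
  back <- applyTransform(invertTransform(transform), pins)
  rel <- sweep(back, 2, plane$origin)
  cbind(rel %*% plane$ex, rel %*% plane$ey)
}

#' World mm positions of the film pixel centres
#' @param film a [FilmImage-class].
#' @return n x 3 matrix, pixels in storage order (u fastest).
#' @export
filmPixelWorld <- function(film) {
  n <- dim(film@pixels)
  u <- film@offset[1] + (seq_len(n[1]) - 1) * film@pitch
  v <- film@offset[2] + (seq_len(n[2]) - 1) * film@pitch
  uv <- as.matrix(expand.grid(u = u, v = v))
  matrix(film@frameOrigin, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %o% film@ex + uv[, 2] %o% film@ey
}

#' Write / read a film image as 16-bit TIFF + JSON sidecar
#'
#' The TIFF stores dose scaled to the 16-bit range; the sidecar records the
#' pitch, offset, plane embedding, dose scale, medium flag and holes.
#'
#' @param film a [FilmImage-class].
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `readFilmTiff` returns a [FilmImage-class] (dose quantized to
#'   16 bits).
#' @export
writeFilmTiff <- function(film, path) {
  mx <- max(film@pixels, 1e-12)
  img <- t(film@pixels[, rev(seq_len(ncol(film@pixels))), drop = FALSE]) / mx
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  meta <- list(pitch = film@pitch, offset = film@offset,
               frameOrigin = film@frameOrigin, ex = film@ex, ey = film@ey,
               medium = film@medium, doseMax = mx,
               holes = if (nrow(film@holes)) film@holes else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFilmTiff
#' @param path TIFF path written by `writeFilmTiff`.
#' @export
readFilmTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  px <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE] * meta$doseMax
  holes <- if (!length(meta$holes)) matrix(numeric(0), 0, 2) else
    matrix(unlist(meta$holes), ncol = 2)
  new("FilmImage", pixels = px, pitch = meta$pitch,
      offset = as.numeric(meta$offset),
      frameOrigin = as.numeric(meta$frameOrigin),
      ex = as.numeric(meta$ex), ey = as.numeric(meta$ey),
      medium = meta$medium, holes = holes)
}
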