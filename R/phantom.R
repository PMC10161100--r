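#' Specification of the inhomogeneous sphere phantom
#'
#' Builds the default phantom geometry: a 160 mm solid-water sphere whose
#' centre holds a 2 x 2 x 6 cm RW3 core flanked on -x by a 1.5 x 2 x 6 cm
#' air cavity, with a mirrored-C bone inset (three axis-aligned boxes: two
#' lateral bars 1.5 cm thick in x and a posterior bar 1 cm thick in y, all
#' 6 cm long in z) wrapping the core/cavity assembly, and three metal
#' fiducial pins at 70 mm radius in the central axial plane. The pin
#' azimuths (90, 210, 350 degrees) are deliberately non-equilateral: with
#' three indistinguishable fiducials a symmetric set leaves the
#' correspondence (and hence the rigid registration) ambiguous, so the
#' triangle must be scalene. All coordinates are Leksell mm; the core is
#' centred on the unit centre point (100, 100, 100).
#'
#' @param sphereDiameter sphere diameter mm.
#' @param spacing CT voxel spacing mm.
#' @param pinRadius radius of the voxelized pin representation, mm.
#' @param margin grid margin beyond the sphere, mm.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec()
#' @export
phantomSpec <- function(sphereDiameter = 160, spacing = c(0.53, 0.53, 1),
                        pinRadius = max(1, 1.25 * max(spacing)),
                        margin = 5) {
  box <- function(lo, hi) list(low = lo, high = hi)
  ang <- c(90, 210, 350) * pi / 180
  pins <- cbind(100 + 70 * cos(ang), 100 + 70 * sin(ang), 100)
  spec <- new("PhantomSpec",
    sphereDiameter = sphereDiameter,
    coreBox = box(c(90, 90, 70), c(110, 110, 130)),
    airBox = box(c(75, 90, 70), c(90, 110, 130)),
    boneBoxes = list(box(c(60, 90, 70), c(75, 110, 130)),
                     box(c(110, 90, 70), c(125, 110, 130)),
                     box(c(60, 110, 70), c(125, 120, 130))),
    pins = pins,
    materialOf = c(ambient = "air", sphere = "lgk_sw", core = "rw3",
                   air = "air", bone = "bone", pin = "metal"),
    spacing = if (length(spacing) == 1L) rep(spacing, 3) else spacing,
    margin = margin)
  attr(spec, "pinRadius") <- pinRadius
  spec
}

.boxesOverlap <- function(a, b) {
  all(a$low < b$high - 1e-9 & b$low < a$high - 1e-9)
}

#' Voxelize the phantom into a material label grid
#'
#' Rasterizes the phantom: solid-water sphere, RW3 core, air cavity,
#' mirrored-C bone boxes and metal pins, with ambient air outside the sphere
#' (so ray tracing has a defined entry medium). Boxes are half-open
#' `[low, high)`; a voxel belongs to a box when its centre does.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [LabelGrid-class] covering the sphere with the spec's margin.
#' @examples
#' labels <- buildPhantom(phantomSpec(spacing = 4))
#' labels
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  # conflicting-label overlap guard (bone boxes may touch each other)
  for (i in seq_along(spec@boneBoxes)) {
    if (.boxesOverlap(spec@boneBoxes[[i]], spec@airBox))
      stop("overlapping regions with conflicting labels: bone box ", i,
           " and air_box")
  }
  mats <- c("air", "lgk_sw", "rw3", "bone", "metal")
  code <- function(region) match(spec@materialOf[[region]], mats)
  r <- spec@sphereDiameter / 2
  lo <- 100 - r - spec@margin
  sp <- spec@spacing
  n <- as.integer(ceiling((2 * r + 2 * spec@margin) / sp)) + 1L
  ax <- lapply(1:3, function(a) lo[min(a, length(lo))] + (seq_len(n[a]) - 1) * sp[a])
  lab <- array(code("ambient"), n)
  d2 <- outer(outer((ax[[1]] - 100)^2, (ax[[2]] - 100)^2, "+"),
              (ax[[3]] - 100)^2, "+")
  lab[d2 <= r^2] <- code("sphere")
  rm(d2)
  fill <- function(b, cd) {
    ii <- lapply(1:3, function(a) which(ax[[a]] >= b$low[a] - 1e-9 &
                                          ax[[a]] < b$high[a] - 1e-9))
    lab[ii[[1]], ii[[2]], ii[[3]]] <<- cd
  }
  for (b in spec@boneBoxes) fill(b, code("bone"))
  fill(spec@coreBox, code("core"))
  fill(spec@airBox, code("air"))
  pr <- attr(spec, "pinRadius")
  if (is.null(pr)) pr <- 1
  for (p in seq_len(nrow(spec@pins))) {
    ctr <- spec@pins[p, ]
    ii <- lapply(1:3, function(a) which(abs(ax[[a]] - ctr[a]) <= pr + sp[a]))
    sub <- expand.grid(i = ii[[1]], j = ii[[2]], k = ii[[3]])
    dd <- (ax[[1]][sub$i] - ctr[1])^2 + (ax[[2]][sub$j] - ctr[2])^2 +
      (ax[[3]][sub$k] - ctr[3])^2
    hit <- sub[dd <= pr^2, ]
    lab[cbind(hit$i, hit$j, hit$k)] <- code("pin")
  }
  new("LabelGrid", voxels = lab, spacing = sp,
      origin = rep(lo, length.out = 3), materials = mats)
}

#' Density maps directly from a label grid
#'
#' Bypasses the CT chain: assigns each labelled voxel its material's tabled
#' relative electron density and the Eq.-style converted mass density.
#' Useful for noiseless ground-truth maps.
#'
#' @param labels a [LabelGrid-class].
#' @param materials a [MaterialTable-class].
#' @return a [DensityMaps-class].
#' @export
densityMapsFromLabels <- function(labels, materials) {
  eta <- materialProperty(materials, labels@materials, "eta")[labels@voxels]
  rho <- materialProperty(materials, labels@materials, "rho")[labels@voxels]
  mk <- function(v) voxelGrid(array(v, dim(labels@voxels)),
                              spacing = labels@spacing,
                              origin = labels@origin)
  bins <- compositionBins()
  bin <- findInterval(rho, bins$rhoLow)
  new("DensityMaps", eta = mk(eta), rho = mk(rho), bin = mk(bin))
}
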