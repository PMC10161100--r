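#' Write / read a grid as MetaImage (.mha)
#'
#' Single-file MetaImage with a local binary payload (MET_DOUBLE,
#' little-endian), recording dimensions, spacing and offset. A JSON sidecar
#' is not needed; dose-specific metadata (medium flag, calibration, seed)
#' can be written with [writeGridSidecar()].
#'
#' @param grid a [VoxelGrid-class] (or subclass).
#' @param path output path (conventionally `.mha`).
#' @return `readMetaImage` returns a [VoxelGrid-class].
#' @export
writeMetaImage <- function(grid, path) {
  d <- dim(grid@voxels)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(grid@origin, collapse = " ")),
           paste("ElementSpacing =", paste(grid@spacing, collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(grid@voxels), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeMetaImage
#' @export
readMetaImage <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  nl <- which(raw == as.raw(10L))
  hdr <- list()
  pos <- 1L
  for (e in nl) {
    line <- rawToChar(raw[pos:(e - 1L)])
    pos <- e + 1L
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementType, "MET_DOUBLE"))
    stop("unsupported element type: ", hdr$ElementType)
  d <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  v <- readBin(raw[pos:length(raw)], "double", n = prod(d), size = 8,
               endian = "little")
  voxelGrid(array(v, d),
            spacing = as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]]),
            origin = as.numeric(strsplit(hdr$Offset, " ")[[1]]))
}

#' Write dose-grid metadata as a JSON sidecar
#' @param dose a [DoseGrid-class].
#' @param path sidecar path.
#' @param seed optional seed to record.
#' @export
writeGridSidecar <- function(dose, path, seed = NULL) {
  meta <- list(medium = dose@medium,
               calibration = attr(dose, "calibration"), seed = seed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write / read a plan as YAML
#'
#' Stores shots (centre, sector states, weight), prescription, beam-on
#' time and the reference dose rate with its date. A loader for the
#' treatment-planning-system XML export dialect can be layered on the same
#' fields.
#'
#' @param plan a [Plan-class].
#' @param path YAML path.
#' @export
writePlanYaml <- function(plan, path) {
  obj <- list(
    shots = lapply(plan@shots, function(s)
      list(center = as.numeric(s@center), sectors = as.list(s@sectors),
           weight = s@weight)),
    prescription_dose_gy = plan@prescriptionDose,
    prescription_isodose_pct = plan@prescriptionIsodose,
    bot_min = if (is.na(plan@bot)) NULL else plan@bot,
    reference_rate_gy_min = plan@refRate,
    reference_date = format(plan@refDate))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writePlanYaml
#' @export
readPlanYaml <- function(path) {
  y <- yaml::read_yaml(path)
  shots <- lapply(y$shots, function(s)
    shot(as.numeric(unlist(s$center)), as.character(unlist(s$sectors)),
         s$weight %||% 1))
  new("Plan", shots = shots,
      prescriptionDose = y$prescription_dose_gy,
      prescriptionIsodose = y$prescription_isodose_pct,
      bot = y$bot_min %||% NA_real_,
      refRate = y$reference_rate_gy_min,
      refDate = as.Date(y$reference_date))
}

#' Write a phantom spec as YAML
#' @param spec a [PhantomSpec-class].
#' @param path YAML path.
#' @export
writePhantomYaml <- function(spec, path) {
  bx <- function(b) list(low = as.numeric(b$low), high = as.numeric(b$high))
  yaml::write_yaml(list(
    sphere_diameter_mm = spec@sphereDiameter,
    core_box = bx(spec@coreBox), air_box = bx(spec@airBox),
    bone_boxes = lapply(spec@boneBoxes, bx),
    pins = lapply(seq_len(nrow(spec@pins)),
                  function(i) as.numeric(spec@pins[i, ])),
    material_of = as.list(spec@materialOf),
    voxel_spacing_mm = as.numeric(spec@spacing),
    margin_mm = spec@margin), path)
  invisible(path)
}
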