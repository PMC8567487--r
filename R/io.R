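#' Read an 8-bit grayscale raster
#'
#' Reads a TIFF or PNG image and returns an integer matrix of gray levels
#' 0-255 (rows = image rows). Multi-channel images are reduced to their
#' first channel; qBEI scans are single-channel by construction.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return integer matrix with values in 0..255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    bm_stop("bm_input_error", sprintf("unsupported image format '.%s'", ext))
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "double"
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Write an 8-bit grayscale raster
#'
#' @param img integer or numeric matrix of gray levels 0..255.
#' @param path output path; format chosen from the extension
#'   (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is.matrix(img))
  if (any(img < 0 | img > 255))
    bm_stop("bm_domain_error", "gray levels must lie in [0, 255]")
  norm <- round(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    png = png::writePNG(norm, path),
    bm_stop("bm_input_error", sprintf("unsupported image format '.%s'", ext))
  )
  invisible(path)
}

# internal: coerce/validate an inclusion mask against an image
check_mask <- function(img, mask) {
  if (is.null(mask)) return(matrix(TRUE, nrow(img), ncol(img)))
  if (!all(dim(mask) == dim(img)))
    bm_stop("bm_shape_error", "mask dimensions do not match image dimensions")
  mask != 0
}

#' Write / read a class-coded section raster
#'
#' The class raster is stored as an 8-bit PNG or TIFF whose gray levels are
#' the class codes themselves (0 = void/marrow, 1 = mineralized,
#' 2 = osteoid), with a JSON sidecar (`<path>.json`) recording the pixel
#' size, the class map and, when present, a side-by-side compartment raster
#' (`<path base>_compartments.<ext>`).
#'
#' @param raster a [class_raster()].
#' @param path image path (`.png` or `.tif`).
#' @return `write_class_raster` returns `path` invisibly;
#'   `read_class_raster` returns a [class_raster()].
#' @export
write_class_raster <- function(raster, path) {
  stopifnot(inherits(raster, "class_raster"))
  write_gray_image(raster$classes, path)
  comp_path <- NULL
  if (!is.null(raster$compartments)) {
    comp_path <- sub("(\\.[^.]+)$", "_compartments\\1", path)
    write_gray_image(raster$compartments, comp_path)
  }
  jsonlite::write_json(
    list(pixel_size_um = raster$pixel_size,
         class_map = list("0" = "VOID", "1" = "MINERALIZED", "2" = "OSTEOID"),
         compartment_raster = if (is.null(comp_path)) NULL else basename(comp_path),
         compartment_map = if (is.null(comp_path)) NULL else
           list("0" = "NONE", "1" = "CORTICAL", "2" = "TRABECULAR")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_class_raster
#' @export
read_class_raster <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  classes <- read_gray_image(path)
  comp <- NULL
  if (length(side$compartment_raster) == 1L)
    comp <- read_gray_image(file.path(dirname(path), side$compartment_raster))
  class_raster(classes, side$pixel_size_um, comp)
}

#' Write / read a surface annotation as GeoJSON-style JSON
#'
#' Surfaces and tetracycline labels are stored as a FeatureCollection of
#' LineString features with `kind` (`"surface"` or `"label"`), `state` /
#' `type` and `inter_label_um` properties; the label interval, osteoclast
#' count and direct osteoid widths ride along as top-level fields.
#'
#' @param ann a [surface_annotation()].
#' @param path JSON path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a [surface_annotation()].
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "surface_annotation"))
  feat <- c(
    lapply(ann$surfaces, function(s) list(
      type = "Feature",
      geometry = list(type = "LineString", coordinates = s$coords),
      properties = list(kind = "surface", state = s$state))),
    lapply(ann$labels, function(l) list(
      type = "Feature",
      geometry = list(type = "LineString", coordinates = l$coords),
      properties = list(kind = "label", type = l$type,
                        inter_label_um = l$inter_label_um)))
  )
  jsonlite::write_json(
    list(type = "FeatureCollection",
         label_interval_days = ann$label_interval_days,
         n_osteoclasts = ann$n_osteoclasts,
         osteoid_widths_um = ann$osteoid_widths_um,
         features = feat),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  surfaces <- list(); labels <- list()
  for (f in x$features) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    if (f$properties$kind == "surface")
      surfaces[[length(surfaces) + 1L]] <-
        list(coords = coords, state = f$properties$state)
    else
      labels[[length(labels) + 1L]] <-
        list(coords = coords, type = f$properties$type,
             inter_label_um = f$properties$inter_label_um)
  }
  n_oc <- x$n_osteoclasts
  surface_annotation(
    surfaces, labels,
    label_interval_days = x$label_interval_days,
    n_osteoclasts = if (is.null(n_oc)) NA_integer_ else n_oc,
    osteoid_widths_um = if (length(x$osteoid_widths_um))
      unlist(x$osteoid_widths_um) else NULL)
}
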