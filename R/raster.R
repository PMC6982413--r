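#' Georeferenced 3-band raster image
#'
#' A `raster_image` holds an 8-bit RGB pixel grid together with a 6-coefficient
#' affine geotransform and a CRS identifier. The geotransform maps 0-based
#' pixel-centre coordinates `(col, row)` to projected map coordinates:
#' \deqn{x = g_1 + g_2 \cdot col + g_3 \cdot row, \quad
#'       y = g_4 + g_5 \cdot col + g_6 \cdot row}
#' with all `g` in metres. The default CRS is the USA Contiguous Albers Equal
#' Area Conic, USGS version (EPSG:5070), an equal-area projection so that
#' pixel counts convert directly to areas.
#'
#' @param array numeric array `height x width x 3`, values in `[0, 255]`.
#' @param geotransform numeric length 6 as above; must be invertible.
#' @param crs CRS identifier string.
#' @param nodata optional logical `height x width` matrix of missing pixels.
#' @param georeferenced logical; `FALSE` marks a unit placeholder transform
#'   (e.g. a plain PNG with no world file).
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(array, geotransform = c(0, 1, 0, 0, 0, 1),
                         crs = "EPSG:5070", nodata = NULL,
                         georeferenced = TRUE) {
  if (length(dim(array)) == 2L) array <- array(rep(array, 3L), c(dim(array), 3L))
  stopifnot(length(dim(array)) == 3L, dim(array)[3] == 3L,
            length(geotransform) == 6L)
  if (anyNA(array) || min(array) < 0 || max(array) > 255)
    stop("pixel values must be finite and in [0, 255]")
  det <- geotransform[2] * geotransform[6] - geotransform[3] * geotransform[5]
  if (!is.finite(det) || det == 0) stop("geotransform is not invertible")
  if (!is.null(nodata))
    stopifnot(is.logical(nodata), all(dim(nodata) == dim(array)[1:2]))
  structure(list(array = array, geotransform = as.numeric(geotransform),
                 crs = crs, nodata = nodata,
                 georeferenced = isTRUE(georeferenced)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("<raster_image> %d x %d px, 3 bands, crs %s%s\n", d[2], d[1],
              x$crs, if (x$georeferenced) "" else " (not georeferenced)"))
  cat("  geotransform:", format(x$geotransform, digits = 8), "\n")
  cat(sprintf("  pixel area: %.6g m^2\n", pixel_area(x)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$array)

#' Ground area of one pixel in square metres
#'
#' `|g2*g6 - g3*g5|` of the affine geotransform.
#' @param img a [raster_image].
#' @return numeric scalar, m^2.
#' @export
pixel_area <- function(img) {
  g <- img$geotransform
  abs(g[2] * g[6] - g[3] * g[5])
}

#' Map coordinates of pixel centres
#'
#' @param img a [raster_image] (or a list with a `geotransform` element).
#' @param col,row 0-based pixel coordinates (pixel-centre convention).
#' @return data.frame with columns `x`, `y` in metres.
#' @export
pixel_to_map <- function(img, col, row) {
  g <- if (is.numeric(img)) img else img$geotransform
  data.frame(x = g[1] + g[2] * col + g[3] * row,
             y = g[4] + g[5] * col + g[6] * row)
}

#' Inverse of [pixel_to_map()]
#' @inheritParams pixel_to_map
#' @param x,y projected coordinates, metres.
#' @return data.frame with fractional 0-based `col`, `row`.
#' @export
map_to_pixel <- function(img, x, y) {
  g <- if (is.numeric(img)) img else img$geotransform
  det <- g[2] * g[6] - g[3] * g[5]
  dx <- x - g[1]
  dy <- y - g[4]
  data.frame(col = (g[6] * dx - g[3] * dy) / det,
             row = (-g[5] * dx + g[2] * dy) / det)
}

## ---- world files -----------------------------------------------------------

world_file_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  wf_ext <- switch(ext, png = "pgw", jpg = "jgw", jpeg = "jgw",
                   tif = "tfw", tiff = "tfw", "wld")
  paste0(tools::file_path_sans_ext(path), ".", wf_ext)
}

#' Read/write an ESRI world file
#'
#' Six lines `A, D, B, E, C, F` encoding `x = A*col + B*row + C`,
#' `y = D*col + E*row + F` at pixel centres; converted to/from the package's
#' geotransform layout `c(C, A, B, F, D, E)`.
#' @param path world-file path.
#' @return `read_world_file`: numeric geotransform of length 6.
#' @export
read_world_file <- function(path) {
  v <- as.numeric(readLines(path, n = 6L))
  if (length(v) != 6L || anyNA(v)) stop("malformed world file: ", path)
  c(v[5], v[1], v[3], v[6], v[2], v[4])
}

#' @rdname read_world_file
#' @param geotransform geotransform to write.
#' @export
write_world_file <- function(geotransform, path) {
  g <- geotransform
  writeLines(format(c(g[2], g[5], g[3], g[6], g[1], g[4]), digits = 15), path)
  invisible(path)
}

## ---- raster I/O ------------------------------------------------------------

#' Read a map image from disk
#'
#' PNG and TIFF images are read with their world-file sidecar
#' (`.pgw`/`.tfw`/`.wld`) when present; without one the raster gets a unit
#' geotransform and is flagged not georeferenced (a warning is emitted), so a
#' polynomial transform must be fitted downstream.
#'
#' @param path image path (`.png`, `.tif`/`.tiff`).
#' @param crs CRS identifier to attach.
#' @return A [raster_image].
#' @export
read_raster <- function(path, crs = "EPSG:5070") {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF")
      tiff::readTIFF(path)
    },
    stop("unsupported raster format: .", ext))
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  a <- round(a[, , 1:3, drop = FALSE] * 255)
  wf <- world_file_path(path)
  if (file.exists(wf)) {
    raster_image(a, read_world_file(wf), crs = crs)
  } else {
    warning("no world file for ", basename(path),
            "; using unit geotransform (not georeferenced)")
    raster_image(a, crs = crs, georeferenced = FALSE)
  }
}

#' Write a map image and its world file
#'
#' 8-bit lossless output (PNG or uncompressed-channel TIFF) plus the ESRI
#' world-file sidecar, so write-then-read round trips are bit exact.
#' @param img a [raster_image].
#' @param path output path (`.png`, `.tif`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  a <- img$array / 255
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to write TIFF")
      tiff::writeTIFF(a, path, bits.per.sample = 8L)
    },
    stop("unsupported raster format: .", ext))
  if (img$georeferenced) write_world_file(img$geotransform, world_file_path(path))
  invisible(path)
}

#' Read/write single-band integer rasters (class and label grids)
#'
#' Plain tab-separated text plus a world-file sidecar: portable, diffable and
#' lossless for the small non-negative integer ids used for classes and
#' segment labels.
#' @param x integer matrix.
#' @param path output path (`.tsv` recommended).
#' @param geotransform optional geotransform written as a `.wld` sidecar.
#' @return `read_int_raster`: integer matrix, with the geotransform (if a
#'   sidecar exists) in attribute `"geotransform"`.
#' @export
write_int_raster <- function(x, path, geotransform = NULL) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(geotransform)) write_world_file(geotransform, world_file_path(path))
  invisible(path)
}

#' @rdname write_int_raster
#' @export
read_int_raster <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  wf <- world_file_path(path)
  if (file.exists(wf)) attr(m, "geotransform") <- read_world_file(wf)
  m
}
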