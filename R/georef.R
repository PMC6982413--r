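#' Polynomial georeferencing from ground control points
#'
#' A scanned or exported map image carries no projection. Ground control
#' points (GCPs) pair pixel locations with known projected coordinates; an
#' order-1 to order-3 polynomial in `(col, row)` fitted per axis by ordinary
#' least squares then maps any pixel to the map plane. Order 3 matches common
#' GIS practice for warped scans; order 1 is a plain affine.
#'
#' The transform object also stores the reverse-direction fit (map to pixel,
#' same order, same GCPs), which nearest-neighbour warping needs; for order 1
#' the exact analytic inverse of the forward affine is used instead.
#'
#' @param gcps data.frame with columns `src_col`, `src_row` (0-based pixel
#'   coordinates) and `map_x`, `map_y` (projected metres).
#' @param order polynomial order, 1, 2 or 3.
#' @return An object of class `poly_transform` with elements `order`,
#'   `coeffs_x`, `coeffs_y`, `inv_coeffs_x`, `inv_coeffs_y` and
#'   `rms_residual` (metres, over the GCPs).
#' @export
fit_polynomial_transform <- function(gcps, order = 3L) {
  stopifnot(all(c("src_col", "src_row", "map_x", "map_y") %in% names(gcps)))
  order <- as.integer(order)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  if (!all(is.finite(as.matrix(gcps[c("src_col", "src_row", "map_x", "map_y")]))))
    stop("GCP coordinates must be finite")
  ncoef <- (order + 1L) * (order + 2L) / 2L
  if (nrow(gcps) < ncoef)
    stop(sprintf("order %d needs at least %d GCPs, got %d",
                 order, ncoef, nrow(gcps)))

  fit_axis <- function(u, v, target) {
    X <- poly_design(u, v, order)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X))
      stop("degenerate GCP configuration (collinear or coincident points)")
    qr.coef(qr_x, target)
  }
  cx <- fit_axis(gcps$src_col, gcps$src_row, gcps$map_x)
  cy <- fit_axis(gcps$src_col, gcps$src_row, gcps$map_y)
  X <- poly_design(gcps$src_col, gcps$src_row, order)
  rx <- gcps$map_x - X %*% cx
  ry <- gcps$map_y - X %*% cy
  rms <- sqrt(mean(rx^2 + ry^2))

  # reverse fit (map -> pixel); exact inverse for the affine case
  if (order == 1L) {
    det <- cx[2] * cy[3] - cx[3] * cy[2]
    if (det == 0) stop("degenerate GCP configuration (singular affine)")
    icx <- c(-(cy[3] * cx[1] - cx[3] * cy[1]) / det, cy[3] / det, -cx[3] / det)
    icy <- c((cy[2] * cx[1] - cx[2] * cy[1]) / det, -cy[2] / det, cx[2] / det)
  } else {
    icx <- fit_axis(gcps$map_x, gcps$map_y, gcps$src_col)
    icy <- fit_axis(gcps$map_x, gcps$map_y, gcps$src_row)
  }

  structure(list(order = order,
                 coeffs_x = unname(cx), coeffs_y = unname(cy),
                 inv_coeffs_x = unname(icx), inv_coeffs_y = unname(icy),
                 rms_residual = rms, n_gcps = nrow(gcps)),
            class = "poly_transform")
}

# monomial design matrix: for each total degree d = 0..order, terms
# col^d, col^(d-1)*row, ..., row^d
poly_design <- function(u, v, order) {
  cols <- list()
  for (d in 0:order)
    for (j in 0:d)
      cols[[length(cols) + 1L]] <- u^(d - j) * v^j
  do.call(cbind, cols)
}

#' @export
print.poly_transform <- function(x, ...) {
  cat(sprintf("<poly_transform> order %d, %d GCPs, rms residual %.4g m\n",
              x$order, x$n_gcps, x$rms_residual))
  invisible(x)
}

#' Apply a polynomial transform
#'
#' @param t a `poly_transform` from [fit_polynomial_transform()].
#' @param col,row pixel coordinates (forward direction).
#' @param inverse if `TRUE`, `col`/`row` are interpreted as map `x`/`y` and
#'   the reverse fit is applied.
#' @return data.frame of transformed coordinates (`x`,`y` or `col`,`row`).
#' @export
apply_transform <- function(t, col, row, inverse = FALSE) {
  X <- poly_design(col, row, t$order)
  if (inverse)
    data.frame(col = drop(X %*% t$inv_coeffs_x),
               row = drop(X %*% t$inv_coeffs_y))
  else
    data.frame(x = drop(X %*% t$coeffs_x), y = drop(X %*% t$coeffs_y))
}

#' Read ground control points from a plain-text table
#'
#' Whitespace- or comma-separated with a header naming
#' `src_col,src_row,map_x,map_y`.
#' @param path file path.
#' @return data.frame of GCPs.
#' @export
read_gcps <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  g <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("src_col", "src_row", "map_x", "map_y") %in% names(g)))
  g
}

#' Suggest an output grid for warping
#'
#' Covers the image of the source extent under the transform, at a resolution
#' equal to the mean GCP-implied ground scale rounded to a whole number of
#' metres.
#' @param t a `poly_transform`.
#' @param width,height source image dimensions in pixels.
#' @return list with `geotransform` and `dim = c(height, width)`.
#' @export
suggest_output_grid <- function(t, width, height) {
  cc <- c(0, width - 1, 0, width - 1, (width - 1) / 2)
  rr <- c(0, 0, height - 1, height - 1, (height - 1) / 2)
  m <- apply_transform(t, cc, rr)
  # local scale at the image centre
  eps <- 1
  c0 <- apply_transform(t, (width - 1) / 2, (height - 1) / 2)
  c1 <- apply_transform(t, (width - 1) / 2 + eps, (height - 1) / 2)
  c2 <- apply_transform(t, (width - 1) / 2, (height - 1) / 2 + eps)
  res <- max(1, round(mean(c(sqrt((c1$x - c0$x)^2 + (c1$y - c0$y)^2),
                             sqrt((c2$x - c0$x)^2 + (c2$y - c0$y)^2)))))
  xr <- range(m$x); yr <- range(m$y)
  out_w <- max(1L, ceiling((xr[2] - xr[1]) / res) + 1L)
  out_h <- max(1L, ceiling((yr[2] - yr[1]) / res) + 1L)
  list(geotransform = c(xr[1], res, 0, yr[2], 0, -res),
       dim = c(out_h, out_w))
}

#' Warp an image onto a georeferenced grid
#'
#' Nearest-neighbour resampling only: the choropleth palette must survive
#' warping exactly, and interpolation would invent colours that exist in no
#' legend class. Each output pixel centre is mapped back to source pixel
#' coordinates through the transform's reverse fit; output pixels whose
#' preimage falls outside the source (or on a source nodata pixel) become
#' nodata.
#'
#' @param img source [raster_image] (its own geotransform is ignored; the
#'   transform is pixel-based).
#' @param t a `poly_transform` mapping source pixels to map coordinates.
#' @param out_grid list with `geotransform` and `dim = c(height, width)`,
#'   e.g. from [suggest_output_grid()].
#' @param crs CRS identifier for the output.
#' @return A georeferenced [raster_image]; nodata pixels are black with the
#'   `nodata` mask set.
#' @export
warp_image <- function(img, t, out_grid = suggest_output_grid(t, dim(img$array)[2], dim(img$array)[1]),
                       crs = img$crs) {
  oh <- out_grid$dim[1]; ow <- out_grid$dim[2]
  g <- out_grid$geotransform
  cr <- expand.grid(col = 0:(ow - 1), row = 0:(oh - 1))
  x <- g[1] + g[2] * cr$col + g[3] * cr$row
  y <- g[4] + g[5] * cr$col + g[6] * cr$row
  src <- apply_transform(t, x, y, inverse = TRUE)
  sc <- round(src$col); sr <- round(src$row)
  sh <- dim(img$array)[1]; sw <- dim(img$array)[2]
  ok <- is.finite(sc) & is.finite(sr) & sc >= 0 & sc < sw & sr >= 0 & sr < sh
  out <- array(0, c(oh, ow, 3))
  nodata <- matrix(TRUE, oh, ow)
  # output is generated in row-major (expand.grid over col fastest); build
  # linear indices for [row, col] matrices (column-major storage)
  oi <- (cr$row + 1L) + cr$col * oh
  sidx <- (sr + 1L) + sc * sh
  if (!is.null(img$nodata)) ok[ok] <- ok[ok] & !img$nodata[sidx[ok]]
  for (b in 1:3) {
    bnd <- img$array[, , b]
    obnd <- matrix(0, oh, ow)
    obnd[oi[ok]] <- bnd[sidx[ok]]
    out[, , b] <- obnd
  }
  nodata[oi[ok]] <- FALSE
  raster_image(out, g, crs = crs, nodata = nodata)
}
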