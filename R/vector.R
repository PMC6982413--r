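#' Polygon zone layer (counties, states, synthetic cells)
#'
#' Zonal statistics run against a layer of spatial units. A `zone_layer`
#' couples a unit table (`unit_id`, `state_id`, `official_area_km2`) with one
#' polygon per unit; a polygon is a list of rings, each ring an `n x 2`
#' matrix of projected coordinates in metres (first ring outer, further
#' rings holes, even-odd rule). Official areas default to the geometric
#' (shoelace) area when not supplied, but an authoritative cadastral area can
#' be carried instead — density denominators use it.
#'
#' @param units data.frame with at least `unit_id`; optional `state_id`
#'   (defaults to the unit id) and `official_area_km2`.
#' @param geometry list of polygons, parallel to `units` rows.
#' @param crs CRS identifier.
#' @return An object of class `zone_layer`.
#' @export
zone_layer <- function(units, geometry, crs = "EPSG:5070") {
  stopifnot(is.data.frame(units), "unit_id" %in% names(units),
            length(geometry) == nrow(units))
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) stop("unit ids must be unique")
  if (is.null(units$state_id)) units$state_id <- units$unit_id
  geom_area <- vapply(geometry, polygon_area_m2, numeric(1)) / 1e6
  if (is.null(units$official_area_km2)) units$official_area_km2 <- geom_area
  if (any(units$official_area_km2 <= 0)) stop("official areas must be > 0")
  structure(list(units = units, geometry = geometry, crs = crs),
            class = "zone_layer")
}

#' @export
print.zone_layer <- function(x, ...) {
  cat(sprintf("<zone_layer> %d units, %d states, crs %s\n",
              nrow(x$units), length(unique(x$units$state_id)), x$crs))
  invisible(x)
}

#' Signed/total polygon area
#'
#' Shoelace formula summed over rings; with GeoJSON ring orientation (outer
#' counter-clockwise, holes clockwise) holes subtract automatically.
#' @param poly list of rings (`n x 2` matrices, metres).
#' @return area in m^2.
#' @export
polygon_area_m2 <- function(poly) {
  abs(sum(vapply(poly, function(r) {
    x <- r[, 1]; y <- r[, 2]
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    sum(x[j] * y - x * y[j]) / 2
  }, numeric(1))))
}

## ---- GeoJSON I/O -----------------------------------------------------------

#' Read a polygon zone layer from GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features. Properties `unit_id`,
#' `state_id` and `area_km2` (or `official_area_km2`) are picked up when
#' present; a missing unit id falls back to the feature index.
#' @param path GeoJSON file.
#' @param crs CRS identifier to attach (GeoJSON axes are taken as projected
#'   metres; no datum handling is attempted).
#' @return A [zone_layer].
#' @export
read_zones <- function(path, crs = "EPSG:5070") {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  units <- list(); geometry <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(pg) lapply(pg, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    p <- f$properties
    units[[i]] <- data.frame(
      unit_id = as.character(if (!is.null(p$unit_id)) p$unit_id else i),
      state_id = as.character(if (!is.null(p$state_id)) p$state_id else NA),
      official_area_km2 = if (!is.null(p$official_area_km2)) p$official_area_km2
                          else if (!is.null(p$area_km2)) p$area_km2 else NA_real_)
    geometry[[i]] <- rings
  }
  u <- do.call(rbind, units)
  if (all(is.na(u$state_id))) u$state_id <- NULL
  if (all(is.na(u$official_area_km2))) u$official_area_km2 <- NULL
  zone_layer(u, geometry, crs = crs)
}

#' Write a zone layer (or classified-map dissolve) to GeoJSON
#' @param layer a [zone_layer].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vector <- function(layer, path) {
  stopifnot(inherits(layer, "zone_layer"))
  feats <- lapply(seq_len(nrow(layer$units)), function(i) {
    rings <- lapply(layer$geometry[[i]], function(r) {
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, , drop = FALSE])
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature",
         properties = list(unit_id = layer$units$unit_id[i],
                           state_id = layer$units$state_id[i],
                           official_area_km2 = layer$units$official_area_km2[i]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- rasterization ---------------------------------------------------------

#' Rasterize a zone layer onto a pixel grid
#'
#' Pixel-centre rule: a pixel belongs to the unit whose polygon contains its
#' centre (even-odd scanline fill, half-open edge rule so shared edges are
#' counted once). Units are painted in table order; on (degenerate) overlap
#' the later unit wins.
#'
#' @param zones a [zone_layer].
#' @param geotransform target grid geotransform (no rotation terms).
#' @param dim target `c(height, width)` in pixels.
#' @return integer matrix of unit row indices (0 = outside every unit).
#' @export
rasterize_zones <- function(zones, geotransform, dim) {
  g <- geotransform
  if (g[3] != 0 || g[5] != 0)
    stop("rasterize_zones requires an axis-aligned geotransform")
  h <- dim[1]; w <- dim[2]
  out <- matrix(0L, h, w)
  xs <- g[1] + g[2] * (0:(w - 1))
  ys <- g[4] + g[6] * (0:(h - 1))
  for (i in seq_along(zones$geometry)) {
    edges <- do.call(rbind, lapply(zones$geometry[[i]], function(r) {
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, , drop = FALSE])
      n <- nrow(r)
      cbind(x1 = r[-n, 1], y1 = r[-n, 2], x2 = r[-1, 1], y2 = r[-1, 2])
    }))
    keep <- edges[, "y1"] != edges[, "y2"]
    edges <- edges[keep, , drop = FALSE]
    if (nrow(edges) == 0) next
    yr <- range(c(edges[, "y1"], edges[, "y2"]))
    rows <- which(ys >= yr[1] & ys <= yr[2])
    for (rr in rows) {
      y <- ys[rr]
      lo <- pmin(edges[, "y1"], edges[, "y2"])
      hi <- pmax(edges[, "y1"], edges[, "y2"])
      hit <- y >= lo & y < hi          # half-open: top endpoint excluded
      if (!any(hit)) next
      e <- edges[hit, , drop = FALSE]
      xc <- e[, "x1"] + (y - e[, "y1"]) / (e[, "y2"] - e[, "y1"]) *
        (e[, "x2"] - e[, "x1"])
      xc <- sort(xc)
      for (k in seq(1, length(xc) - 1, by = 2)) {
        inside <- which(xs >= xc[k] & xs < xc[k + 1])
        if (length(inside)) out[rr, inside] <- i
      }
    }
  }
  out
}
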