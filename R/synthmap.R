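#' Synthetic choropleth map specification
#'
#' The synthetic generator renders a choropleth of random Voronoi units in a
#' small legend palette, strokes black unit borders, drops black label
#' glyphs, and degrades the render with Gaussian blur and noise — the
#' conditions a scanned or re-exported published map presents to the
#' pipeline (poor resolution, colour-mixed borders, black ink on top of the
#' thematic fill). Per-pixel ground truth is kept, so recovery is scorable.
#'
#' Defaults: 30 units over a 60 x 40 km extent at 100 m/pixel (600 x 400
#' px), four equiprobable density classes with one neighbour-majority
#' smoothing pass, 1-pixel borders, one expected label glyph per unit, blur
#' sigma 0.5 px and additive noise SD 4 (8-bit units).
#'
#' @param n_units number of Voronoi units.
#' @param extent_km `c(width, height)` of the map extent, km.
#' @param resolution ground resolution, m/pixel.
#' @param legend a [map_legend] supplying the palette.
#' @param class_probs per-density-class probabilities (sum 1).
#' @param smoothing_iters neighbour-majority passes for spatial coherence.
#' @param border_width black border stroke width, px (0 = none).
#' @param label_density expected black glyph blocks per unit.
#' @param blur_sigma Gaussian blur sigma, px.
#' @param noise_sd additive Gaussian noise SD, 8-bit units.
#' @param seed integer seed driving every stochastic step (required).
#' @return An object of class `synthetic_map_spec`.
#' @export
synthetic_map_spec <- function(n_units = 30L, extent_km = c(60, 40),
                               resolution = 100, legend = deer_density_legend(),
                               class_probs = rep(0.25, 4),
                               smoothing_iters = 1L, border_width = 1L,
                               label_density = 1, blur_sigma = 0.5,
                               noise_sd = 4, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_units >= 1, length(extent_km) == 2L, all(extent_km > 0),
            resolution > 0, abs(sum(class_probs) - 1) < 1e-9,
            length(class_probs) == length(density_classes(legend)),
            border_width >= 0, blur_sigma >= 0, noise_sd >= 0)
  if (any(extent_km * 1000 < 2 * resolution))
    stop("resolution too coarse for the extent")
  structure(list(n_units = as.integer(n_units), extent_km = extent_km,
                 resolution = resolution, legend = legend,
                 class_probs = class_probs,
                 smoothing_iters = as.integer(smoothing_iters),
                 border_width = as.integer(border_width),
                 label_density = label_density, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_map_spec")
}

#' Random Voronoi tessellation of the map extent
#'
#' Voronoi cells of `n_units` uniform random seed points, clipped to the
#' extent rectangle: each cell is the intersection of the rectangle with the
#' half-planes nearer its seed than any other (Sutherland-Hodgman clipping),
#' so cell areas sum exactly to the extent area. Duplicate seed points are
#' re-jittered with a note. Units are grouped into up to four "states" by
#' seed quadrant, giving a state level for aggregation tests. Deterministic
#' per seed.
#'
#' @param spec a [synthetic_map_spec].
#' @return A [zone_layer]; seed points are attached as attribute `"seeds"`.
#' @export
generate_tessellation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_map_spec"))
  set.seed(spec$seed)
  w <- spec$extent_km[1] * 1000; h <- spec$extent_km[2] * 1000
  n <- spec$n_units
  pts <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
  while (anyDuplicated(round(pts, 6))) {
    message("re-jittering duplicate tessellation seed points")
    dup <- duplicated(round(pts, 6))
    pts[dup, ] <- pts[dup, , drop = FALSE] +
      matrix(stats::runif(2 * sum(dup), -1, 1), ncol = 2)
  }
  rect <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  geometry <- lapply(seq_len(n), function(i) {
    cell <- rect
    for (j in seq_len(n)) {
      if (j == i || nrow(cell) == 0) next
      # half-plane of points nearer pts[i,] than pts[j,]
      mid <- (pts[i, ] + pts[j, ]) / 2
      nrm <- pts[i, ] - pts[j, ]     # points with (p - mid).nrm >= 0 kept
      cell <- clip_halfplane(cell, mid, nrm)
    }
    list(cell)
  })
  quadrant <- 1L + (pts[, 1] > w / 2) + 2L * (pts[, 2] > h / 2)
  units <- data.frame(unit_id = sprintf("U%02d", seq_len(n)),
                      state_id = sprintf("S%d", quadrant))
  zl <- zone_layer(units, geometry, crs = "EPSG:5070")
  attr(zl, "seeds") <- pts
  zl
}

# Sutherland-Hodgman clip of a convex polygon against one half-plane
clip_halfplane <- function(poly, mid, nrm) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  keep <- as.vector((poly[, 1] - mid[1]) * nrm[1] +
                      (poly[, 2] - mid[2]) * nrm[2]) >= 0
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    p1 <- poly[k, ]; p2 <- poly[k2, ]
    in1 <- keep[k]; in2 <- keep[k2]
    if (in1) out <- rbind(out, p1)
    if (xor(in1, in2)) {
      d1 <- (p1[1] - mid[1]) * nrm[1] + (p1[2] - mid[2]) * nrm[2]
      d2 <- (p2[1] - mid[1]) * nrm[1] + (p2[2] - mid[2]) * nrm[2]
      t <- d1 / (d1 - d2)
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}

#' Render a synthetic choropleth with ground truth
#'
#' Classes are drawn iid from `class_probs`, then smoothed by
#' `smoothing_iters` neighbour-majority passes over the unit adjacency graph
#' (ties keep the unit's current class) for spatial coherence. The raster
#' fills each unit with its legend colour, strokes unit borders black at
#' `border_width` and stamps per-unit black glyph blocks (Poisson with mean
#' `label_density`, 3 x 2 px). The truth raster records the *underlying*
#' unit class everywhere — border and label pixels included — which is what
#' a perfect digitization should recover.
#'
#' @param zones a [zone_layer] from [generate_tessellation()].
#' @param spec a [synthetic_map_spec].
#' @param classes optional per-unit class ids (skips the random draw).
#' @return list with `image` (a [raster_image], clean render) and `truth`
#'   (class `ground_truth`: `classes` matrix, `unit_class` table, `units`
#'   raster of unit row indices, `zones`).
#' @export
render_choropleth <- function(zones, spec, classes = NULL) {
  stopifnot(inherits(zones, "zone_layer"), inherits(spec, "synthetic_map_spec"))
  lg <- spec$legend
  dens <- density_classes(lg)
  res <- spec$resolution
  w_px <- round(spec$extent_km[1] * 1000 / res)
  h_px <- round(spec$extent_km[2] * 1000 / res)
  if (spec$border_width > 0 && (w_px < 4 || h_px < 4))
    stop("resolution too coarse to render borders")
  h_m <- spec$extent_km[2] * 1000
  gt <- c(res / 2, res, 0, h_m - res / 2, 0, -res)

  uras <- rasterize_zones(zones, gt, c(h_px, w_px))
  if (any(uras == 0L)) {
    # pixel centres exactly on cell edges: fall back to nearest seed
    seeds <- attr(zones, "seeds")
    miss <- which(uras == 0L, arr.ind = TRUE)
    x <- gt[1] + gt[2] * (miss[, 2] - 1L)
    y <- gt[4] + gt[6] * (miss[, 1] - 1L)
    for (k in seq_len(nrow(miss))) {
      d2 <- (seeds[, 1] - x[k])^2 + (seeds[, 2] - y[k])^2
      uras[miss[k, 1], miss[k, 2]] <- which.min(d2)
    }
  }

  set.seed(spec$seed + 1L)
  n <- nrow(zones$units)
  if (is.null(classes)) {
    classes <- sample(dens, n, replace = TRUE, prob = spec$class_probs)
    if (spec$smoothing_iters > 0) {
      nbr <- unit_adjacency(uras)
      for (it in seq_len(spec$smoothing_iters)) {
        new_cls <- classes
        for (i in seq_len(n)) {
          nb <- c(nbr$b[nbr$a == i], nbr$a[nbr$b == i])
          if (!length(nb)) next
          votes <- table(factor(c(classes[i], classes[nb]), levels = dens))
          top <- names(votes)[votes == max(votes)]
          if (!as.character(classes[i]) %in% top)
            new_cls[i] <- as.integer(top[1])
        }
        classes <- new_cls
      }
    }
  }
  stopifnot(length(classes) == n, all(classes %in% dens))

  truth <- matrix(classes[uras], h_px, w_px)
  pal <- lg$classes[match(classes, lg$classes$class_id),
                    c("red", "green", "blue")]
  img <- array(0, c(h_px, w_px, 3))
  for (b in 1:3) img[, , b] <- matrix(pal[[b]][uras], h_px, w_px)

  ink <- matrix(FALSE, h_px, w_px)
  if (spec$border_width > 0) {
    ink[, -w_px][uras[, -w_px] != uras[, -1]] <- TRUE
    ink[-h_px, ][uras[-h_px, ] != uras[-1, ]] <- TRUE
    if (spec$border_width > 1)
      for (k in seq_len(spec$border_width - 1L)) ink <- dilate4(ink)
  }
  if (spec$label_density > 0) {
    for (i in seq_len(n)) {
      n_glyph <- stats::rpois(1, spec$label_density)
      if (n_glyph == 0) next
      cand <- which(uras == i & !ink)
      if (!length(cand)) next
      for (gidx in seq_len(n_glyph)) {
        p <- cand[sample.int(length(cand), 1L)]
        r0 <- (p - 1L) %% h_px + 1L
        c0 <- (p - 1L) %/% h_px + 1L
        rows <- r0:min(r0 + 1L, h_px)
        cols <- c0:min(c0 + 2L, w_px)
        ink[rows, cols] <- TRUE
      }
    }
  }
  for (b in 1:3) { bnd <- img[, , b]; bnd[ink] <- 0; img[, , b] <- bnd }

  gt_obj <- structure(list(classes = truth,
                           unit_class = data.frame(
                             unit_id = zones$units$unit_id,
                             class_id = classes),
                           units = uras, zones = zones,
                           geotransform = gt),
                      class = "ground_truth")
  list(image = raster_image(img, gt, crs = zones$crs), truth = gt_obj)
}

dilate4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-h, ]
  out[-h, ] <- out[-h, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -w]
  out[, -w] <- out[, -w] | m[, -1]
  out
}

# unit adjacency pairs (a < b) from a unit index raster
unit_adjacency <- function(uras) {
  h <- nrow(uras); w <- ncol(uras)
  p <- rbind(cbind(as.vector(uras[, -w]), as.vector(uras[, -1])),
             cbind(as.vector(uras[-h, ]), as.vector(uras[-1, ])))
  p <- p[p[, 1] != p[, 2] & p[, 1] > 0 & p[, 2] > 0, , drop = FALSE]
  p <- unique(cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2])))
  data.frame(a = p[, 1], b = p[, 2])
}

#' Degrade a rendered map
#'
#' Gaussian blur (per band, replicated boundary) followed by additive
#' Gaussian noise, clipped to `[0, 255]` and rounded — a light model of
#' re-encoding and scan softness. Seed-deterministic; `blur_sigma = 0`,
#' `noise_sd = 0` is the identity.
#'
#' @param img a [raster_image].
#' @param spec a [synthetic_map_spec] (uses `blur_sigma`, `noise_sd`,
#'   `seed`).
#' @return The degraded [raster_image].
#' @export
degrade <- function(img, spec) {
  stopifnot(inherits(img, "raster_image"))
  a <- img$array
  if (spec$blur_sigma > 0) {
    for (b in 1:3)
      a[, , b] <- EBImage::gblur(a[, , b], sigma = spec$blur_sigma,
                                 boundary = "replicate")
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 2L)
    a <- a + stats::rnorm(length(a), 0, spec$noise_sd)
  }
  a <- round(pmin(pmax(a, 0), 255))
  raster_image(a, img$geotransform, crs = img$crs, nodata = img$nodata,
               georeferenced = img$georeferenced)
}

#' Generate a complete synthetic study map
#'
#' Tessellation, class assignment, render and degradation in one call.
#' @param spec a [synthetic_map_spec].
#' @return list `zones`, `clean` (undegraded [raster_image]), `image`
#'   (degraded), `truth` (`ground_truth`).
#' @export
simulate_map <- function(spec) {
  zones <- generate_tessellation(spec)
  r <- render_choropleth(zones, spec)
  list(zones = zones, clean = r$image, image = degrade(r$image, spec),
       truth = r$truth)
}

#' Score recovery of a classified map against ground truth
#'
#' Pixel confusion matrix (truth in rows), overall pixel accuracy, per-class
#' producer's and user's accuracy, and per-unit majority accuracy (the
#' fraction of units whose majority class in `cmap` equals the planted unit
#' class; computed from the truth's unit raster, or taken from a
#' majority-assigned zonal table when one is supplied).
#'
#' @param truth a `ground_truth` from [render_choropleth()].
#' @param cmap a [classified_map] on the same grid.
#' @param zt optional majority-assigned [zonal_table][assign_majority()].
#' @return list `confusion`, `pixel_accuracy`, `producer_accuracy`,
#'   `user_accuracy`, `unit_majority_accuracy`.
#' @export
evaluate_recovery <- function(truth, cmap, zt = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cmap, "classified_map"))
  if (!all(dim(truth$classes) == dim(cmap$class_id)))
    stop("truth and classified map are not on the same grid")
  lv <- sort(unique(c(truth$classes, cmap$class_id)))
  conf <- table(truth = factor(truth$classes, levels = lv),
                mapped = factor(cmap$class_id, levels = lv))
  acc <- sum(diag(conf)) / sum(conf)
  prod_acc <- diag(conf) / pmax(1, rowSums(conf))
  user_acc <- diag(conf) / pmax(1, colSums(conf))

  if (!is.null(zt) && !is.null(zt$params)) {
    maj <- zt$units$majority[match(truth$unit_class$unit_id,
                                   zt$units$unit_id)]
  } else {
    n <- nrow(truth$unit_class)
    maj <- vapply(seq_len(n), function(i) {
      cls <- cmap$class_id[truth$units == i]
      cls <- cls[cls %in% density_classes(cmap$legend)]
      if (!length(cls)) return(NA_integer_)
      tab <- table(cls)
      as.integer(names(tab)[which.max(tab)])
    }, integer(1))
  }
  unit_acc <- mean(maj == truth$unit_class$class_id, na.rm = FALSE)
  list(confusion = conf, pixel_accuracy = acc,
       producer_accuracy = prod_acc, user_accuracy = user_acc,
       unit_majority_accuracy = unit_acc)
}
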