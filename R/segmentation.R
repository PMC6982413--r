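#' Segmentation parameters
#'
#' The scale parameter `scale` bounds the heterogeneity increase allowed per
#' merge: two adjacent objects merge only while the cost
#' \eqn{\Delta h = \sum_b w_b [ n_{AB}\sigma_b(AB) - n_A\sigma_b(A) - n_B\sigma_b(B) ]}
#' (population standard deviations per band) stays below `scale^2`. Small
#' scales keep mixed-colour border pixels out of the large class objects,
#' which is what palette maps with thin dark boundaries need; the default 10
#' suits 8-bit choropleth palettes. Band weights default to equal. The merge
#' cost is colour-only (no shape term), and 4-connectivity is the default so
#' classes cannot leak diagonally across one-pixel border lines.
#'
#' @param scale positive merge threshold (unitless).
#' @param band_weights three non-negative band weights, sum > 0.
#' @param connectivity 4 or 8.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(scale = 10, band_weights = c(1, 1, 1),
                                connectivity = 4L) {
  stopifnot(scale > 0, length(band_weights) == 3L, all(band_weights >= 0),
            sum(band_weights) > 0, connectivity %in% c(4L, 8L))
  structure(list(scale = scale, band_weights = as.numeric(band_weights),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Multiresolution region-merging segmentation
#'
#' Partitions the image into homogeneous image objects, starting from
#' single-pixel objects and merging adjacent objects under a local mutual
#' best-fit rule (see [segmentation_params()] for the cost). Scheduling is
#' deterministic: objects are visited in ascending id, cost ties go to the
#' lower neighbour id and a merged object keeps the smaller id, so the same
#' image and parameters always give the same partition.
#'
#' @param img a [raster_image].
#' @param params a [segmentation_params].
#' @return An object of class `segment_map`: `labels` (integer matrix, ids
#'   from 1, 0 for nodata), `objects` (per-object table from
#'   [compute_object_stats()]), `adjacency` (shared boundary lengths) and the
#'   parameters used.
#' @export
multiresolution_segment <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "raster_image"), inherits(params, "segmentation_params"))
  d <- dim(img$array)
  if (d[1] * d[2] == 0L) stop("empty image")
  nodata <- if (is.null(img$nodata)) matrix(FALSE, d[1], d[2]) else img$nodata
  if (all(nodata)) stop("all pixels are nodata")
  lab <- cpp_mrs_segment(as.numeric(img$array[, , 1]),
                         as.numeric(img$array[, , 2]),
                         as.numeric(img$array[, , 3]),
                         as.logical(nodata), d[1], d[2],
                         params$scale, params$band_weights,
                         params$connectivity)
  labels <- matrix(lab, d[1], d[2])
  st <- compute_object_stats(img, labels)
  structure(list(labels = labels, objects = st$objects,
                 adjacency = st$adjacency, params = params,
                 geotransform = img$geotransform, crs = img$crs),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %d objects over %d x %d px (scale %.3g)\n",
              nrow(x$objects), dim(x$labels)[2], dim(x$labels)[1],
              x$params$scale))
  invisible(x)
}

# Pure-R naive reference used only to cross-check the compiled routes on tiny
# images: labels are kept explicitly, statistics recomputed from pixels at
# every evaluation, same deterministic scheduling.
mrs_segment_reference_r <- function(img, params) {
  d <- dim(img$array)
  lab <- matrix(seq_len(d[1] * d[2]), d[1], d[2])
  nodata <- if (is.null(img$nodata)) matrix(FALSE, d[1], d[2]) else img$nodata
  lab[nodata] <- 0L
  lab[!nodata] <- seq_len(sum(!nodata))
  bands <- lapply(1:3, function(b) img$array[, , b])
  s2 <- params$scale^2
  w <- params$band_weights
  conn <- params$connectivity

  stats_of <- function(id) {
    px <- lab == id
    n <- sum(px)
    sapply(bands, function(v) {
      vv <- v[px]
      c(n = n, s = sum(vv), ss = sum(vv^2))
    })
  }
  sd_pop <- function(n, s, ss) {
    v <- ss / n - (s / n)^2
    if (v > 0) sqrt(v) else 0
  }
  cost <- function(a, b) {
    sum(vapply(1:3, function(k) {
      n <- a["n", k] + b["n", k]; s <- a["s", k] + b["s", k]
      ss <- a["ss", k] + b["ss", k]
      w[k] * (n * sd_pop(n, s, ss) -
                a["n", k] * sd_pop(a["n", k], a["s", k], a["ss", k]) -
                b["n", k] * sd_pop(b["n", k], b["s", k], b["ss", k]))
    }, numeric(1)))
  }
  neighbours_of_id <- function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    nb <- integer(0)
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1]; c <- px[i, 2]
      cand <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      if (conn == 8L)
        cand <- rbind(cand, c(r - 1, c - 1), c(r - 1, c + 1),
                      c(r + 1, c - 1), c(r + 1, c + 1))
      cand <- cand[cand[, 1] >= 1 & cand[, 1] <= d[1] &
                     cand[, 2] >= 1 & cand[, 2] <= d[2], , drop = FALSE]
      nb <- c(nb, lab[cand])
    }
    sort(unique(nb[nb > 0 & nb != id]))
  }
  best_of <- function(id) {
    nbs <- neighbours_of_id(id)
    if (!length(nbs)) return(NULL)
    sa <- stats_of(id)
    best <- NULL; bestc <- Inf
    for (nb in nbs) {
      cc <- cost(sa, stats_of(nb))
      if (is.null(best) || cc < bestc) { best <- nb; bestc <- cc }
    }
    list(id = best, cost = bestc)
  }

  nobj <- max(lab)
  alive <- rep(TRUE, nobj)
  repeat {
    merged_any <- FALSE
    for (id in seq_len(nobj)) {
      if (!alive[id]) next
      b1 <- best_of(id)
      if (is.null(b1) || b1$cost >= s2) next
      b2 <- best_of(b1$id)
      if (is.null(b2) || b2$id != id) next
      keep <- min(id, b1$id); gone <- max(id, b1$id)
      lab[lab == gone] <- keep
      alive[gone] <- FALSE
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  newid <- integer(nobj)
  newid[which(alive)] <- seq_len(sum(alive))
  out <- lab
  out[lab > 0] <- newid[lab[lab > 0]]
  out
}

#' Per-object colour statistics and adjacency
#'
#' Single pass over the label grid: per object the pixel count, per-band mean
#' and population standard deviation (divide by n, consistent with the merge
#' cost), plus shared boundary lengths (counts of 4-neighbour pixel edges)
#' between adjacent objects.
#'
#' @param img a [raster_image].
#' @param labels integer matrix of object ids (0 = nodata), same grid.
#' @return list with `objects` (data.frame `id, n, mean_R, mean_G, mean_B,
#'   sd_R, sd_G, sd_B`) and `adjacency` (data.frame `a, b, boundary` with
#'   `a < b`; the relation is symmetric).
#' @export
compute_object_stats <- function(img, labels) {
  d <- dim(img$array)
  if (!all(dim(labels) == d[1:2])) stop("label/raster dimension mismatch")
  valid <- labels > 0L
  ids <- labels[valid]
  if (!length(ids)) {
    return(list(objects = data.frame(id = integer(), n = integer(),
                                     mean_R = numeric(), mean_G = numeric(),
                                     mean_B = numeric(), sd_R = numeric(),
                                     sd_G = numeric(), sd_B = numeric()),
                adjacency = data.frame(a = integer(), b = integer(),
                                       boundary = integer())))
  }
  uid <- sort(unique(ids))
  n <- as.vector(rowsum(rep(1L, length(ids)), ids))
  obj <- data.frame(id = uid, n = n)
  for (b in 1:3) {
    v <- img$array[, , b][valid]
    s <- as.vector(rowsum(v, ids))
    ss <- as.vector(rowsum(v * v, ids))
    m <- s / n
    obj[[c("mean_R", "mean_G", "mean_B")[b]]] <- m
    obj[[c("sd_R", "sd_G", "sd_B")[b]]] <- sqrt(pmax(0, ss / n - m^2))
  }
  obj <- obj[c("id", "n", "mean_R", "mean_G", "mean_B", "sd_R", "sd_G", "sd_B")]

  pair_edges <- function(l1, l2) {
    sel <- l1 > 0L & l2 > 0L & l1 != l2
    cbind(pmin(l1[sel], l2[sel]), pmax(l1[sel], l2[sel]))
  }
  e <- rbind(pair_edges(labels[, -ncol(labels), drop = FALSE],
                        labels[, -1, drop = FALSE]),
             pair_edges(labels[-nrow(labels), , drop = FALSE],
                        labels[-1, , drop = FALSE]))
  if (nrow(e)) {
    key <- paste(e[, 1], e[, 2])
    tab <- table(key)
    ab <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    adjacency <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                            boundary = as.integer(tab))
    adjacency <- adjacency[order(adjacency$a, adjacency$b), ]
    rownames(adjacency) <- NULL
  } else {
    adjacency <- data.frame(a = integer(), b = integer(), boundary = integer())
  }
  list(objects = obj, adjacency = adjacency)
}

#' Colour-threshold segmentation backend
#'
#' The direct alternative to object building: every pixel within `tolerance`
#' (maximum per-band absolute difference) of a legend display colour takes
#' that class; remaining pixels form "holes". A hole enclosed by a single
#' class is filled to it; a hole touching several classes goes whole to the
#' class nearest in colour to the hole's mean colour, ties to the class with
#' the longest shared hole boundary, then to the lowest class id. Holes
#' touching no class at all (fully unresolvable) become the legend's nodata
#' class with a warning.
#'
#' @param img a [raster_image].
#' @param legend a [legend] whose display colours are pairwise separated by
#'   more than `2 * tolerance` in max-band distance (checked).
#' @param tolerance maximum per-band absolute difference (8-bit units).
#' @return A [classified_map] with provenance `model`.
#' @export
color_threshold_segment <- function(img, legend, tolerance = 30) {
  stopifnot(inherits(img, "raster_image"), inherits(legend, "map_legend"))
  cols <- as.matrix(legend$classes[, c("red", "green", "blue")])
  ids <- legend$classes$class_id
  k <- nrow(cols)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (max(abs(cols[i, ] - cols[j, ])) <= 2 * tolerance)
      stop(sprintf("legend colours of classes %s and %s overlap under tolerance %g",
                   ids[i], ids[j], tolerance))
  }
  d <- dim(img$array)
  npix <- d[1] * d[2]
  r <- as.vector(img$array[, , 1]); g <- as.vector(img$array[, , 2])
  b <- as.vector(img$array[, , 3])
  dist <- matrix(0, npix, k)
  for (i in seq_len(k))
    dist[, i] <- pmax(abs(r - cols[i, 1]), abs(g - cols[i, 2]),
                      abs(b - cols[i, 3]))
  nearest <- max.col(-dist, ties.method = "first")
  dmin <- dist[cbind(seq_len(npix), nearest)]
  cls <- ifelse(dmin <= tolerance, ids[nearest], NA_integer_)
  cm <- matrix(as.integer(cls), d[1], d[2])

  if (anyNA(cm)) {
    holes <- matrix(cpp_label_components(as.integer(is.na(cm)), d[1], d[2], 4L),
                    d[1], d[2])
    shift_pairs <- function(m) {
      # (hole label, neighbouring class) pairs across 4-neighbour edges
      rbind(cbind(as.vector(holes[, -d[2]]), as.vector(m[, -1])),
            cbind(as.vector(holes[, -1]), as.vector(m[, -d[2]])),
            cbind(as.vector(holes[-d[1], ]), as.vector(m[-1, ])),
            cbind(as.vector(holes[-1, ]), as.vector(m[-d[1], ])))
    }
    pr <- shift_pairs(cm)
    pr <- pr[pr[, 1] > 0 & !is.na(pr[, 2]), , drop = FALSE]
    unresolved <- FALSE
    for (hid in seq_len(max(holes))) {
      nb <- pr[pr[, 1] == hid, 2]
      px <- holes == hid
      if (!length(nb)) { cm[px] <- nodata_class(legend); unresolved <- TRUE; next }
      cand <- sort(unique(nb))
      if (length(cand) == 1L) { cm[px] <- cand; next }
      # multi-class hole: each pixel goes to the bordering class nearest in
      # colour to that pixel; exact ties to the class with the longest
      # shared hole boundary, then the lowest class id
      bnd <- vapply(cand, function(cc) sum(nb == cc), numeric(1))
      ord <- cand[order(-bnd, cand)]
      ci <- match(ord, ids)
      pd <- vapply(ci, function(i)
        pmax(abs(r[px] - cols[i, 1]), abs(g[px] - cols[i, 2]),
             abs(b[px] - cols[i, 3])), numeric(sum(px)))
      pd <- matrix(pd, ncol = length(ci))
      cm[px] <- ord[max.col(-pd, ties.method = "first")]
    }
    if (unresolved)
      warning("holes bordered by no classified pixel were set to nodata")
  }
  classified_map(cm, legend, geotransform = img$geotransform, crs = img$crs,
                 provenance = "model")
}
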