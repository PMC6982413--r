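#' Cleanup parameters
#'
#' Cartographic ink (county borders, names) prints black on choropleth maps
#' and must be dissolved back into the surrounding thematic classes. An
#' object counts as black when all three band means are at or below
#' `black_max_channel`. Black objects of at most `small_object_max_px`
#' pixels (labels, small specks) are absorbed whole; larger line work is
#' dissolved pixel-by-pixel from its boundary, at most
#' `max_absorption_passes` passes.
#'
#' @param black_max_channel 8-bit threshold defining black (0-255).
#' @param small_object_max_px small-object pixel cutoff (>= 1).
#' @param max_absorption_passes cap on boundary-absorption passes.
#' @return An object of class `cleanup_params`.
#' @export
cleanup_params <- function(black_max_channel = 60, small_object_max_px = 5L,
                           max_absorption_passes = 100L) {
  stopifnot(black_max_channel >= 0, black_max_channel <= 255,
            small_object_max_px >= 1, max_absorption_passes >= 1)
  structure(list(black_max_channel = black_max_channel,
                 small_object_max_px = as.integer(small_object_max_px),
                 max_absorption_passes = as.integer(max_absorption_passes)),
            class = "cleanup_params")
}

#' Detect black (ink) image objects
#'
#' Object-level test, mirroring object-based processing: an object is black
#' iff its mean is at or below `black_max_channel` in all three bands.
#' @param objects per-object table from [compute_object_stats()].
#' @param params a [cleanup_params].
#' @return integer vector of black object ids.
#' @export
detect_black_objects <- function(objects, params = cleanup_params()) {
  t <- params$black_max_channel
  objects$id[objects$mean_R <= t & objects$mean_G <= t & objects$mean_B <= t]
}

#' Dissolve black objects into the surrounding classes
#'
#' Two stages. Stage 1: every black-classified object with at most
#' `small_object_max_px` pixels takes the density class with the greatest
#' shared boundary length among its non-black neighbours (boundary length,
#' not neighbour count — a one-pixel sliver must not outvote a long edge).
#' Stage 2: remaining black pixels (border line work) are absorbed
#' iteratively: in each pass every black pixel with at least one
#' density-classified 4-neighbour takes the class contributing the most
#' neighbours, ties to the lowest class id; passes repeat until no black
#' pixel remains or the pass cap is hit, when leftovers become nodata with a
#' warning. Pixel counts are conserved and a second application is a no-op.
#'
#' @param cmap a [classified_map] carrying `objects` and `labels`.
#' @param seg the [segment_map][multiresolution_segment()] behind `cmap`
#'   (supplies object sizes and boundary lengths).
#' @param params a [cleanup_params].
#' @return The cleaned [classified_map]; changed pixels carry provenance
#'   `rule`.
#' @export
absorb_black_objects <- function(cmap, seg, params = cleanup_params()) {
  stopifnot(inherits(cmap, "classified_map"))
  lg <- cmap$legend
  black <- black_class(lg)
  if (is.na(black)) return(cmap)
  dens <- density_classes(lg)
  cm <- cmap$class_id
  prov <- cmap$provenance
  rule <- provenance_code("rule")

  # ---- stage 1: whole small objects by shared boundary length
  if (!is.null(cmap$objects) && !is.null(cmap$labels) && !is.null(seg)) {
    obj <- cmap$objects
    sizes <- seg$objects$n[match(obj$id, seg$objects$id)]
    cls_of <- function(id) obj$class_id[match(id, obj$id)]
    small_black <- obj$id[obj$class_id == black &
                            sizes <= params$small_object_max_px]
    adj <- seg$adjacency
    for (id in small_black) {
      nb <- rbind(
        data.frame(other = adj$b[adj$a == id], boundary = adj$boundary[adj$a == id]),
        data.frame(other = adj$a[adj$b == id], boundary = adj$boundary[adj$b == id]))
      if (!nrow(nb)) next
      nb$class <- cls_of(nb$other)
      nb <- nb[nb$class %in% dens, , drop = FALSE]
      if (!nrow(nb)) next  # enclosed by ink; stage 2 resolves
      per <- stats::aggregate(boundary ~ class, nb, sum)
      per <- per[order(-per$boundary, per$class), ]
      new_cls <- per$class[1]
      px <- cmap$labels == id
      cm[px] <- new_cls
      prov[px] <- rule
      obj$class_id[obj$id == id] <- new_cls
      obj$provenance[obj$id == id] <- "rule"
    }
    cmap$objects <- obj
  }

  # ---- stage 2: iterative boundary absorption of line work
  pass <- 0L
  while (any(cm == black) && pass < params$max_absorption_passes) {
    pass <- pass + 1L
    h <- nrow(cm); w <- ncol(cm)
    best_cls <- matrix(0L, h, w)
    best_cnt <- matrix(0L, h, w)
    for (cl in sort(dens)) {          # ascending id: ties keep the lowest
      is_cl <- cm == cl
      cnt <- matrix(0L, h, w)
      cnt[-1, ] <- cnt[-1, ] + is_cl[-h, ]
      cnt[-h, ] <- cnt[-h, ] + is_cl[-1, ]
      cnt[, -1] <- cnt[, -1] + is_cl[, -w]
      cnt[, -w] <- cnt[, -w] + is_cl[, -1]
      take <- cnt > best_cnt
      best_cnt[take] <- cnt[take]
      best_cls[take] <- cl
    }
    absorb <- cm == black & best_cnt > 0L
    if (!any(absorb)) break
    cm[absorb] <- best_cls[absorb]
    prov[absorb] <- rule
    if (!is.null(cmap$labels)) cmap$labels[absorb] <- 0L
  }
  if (any(cm == black)) {
    warning(sum(cm == black), " black pixels could not be absorbed; set to nodata")
    left <- cm == black
    cm[left] <- nodata_class(lg)
    prov[left] <- rule
    if (!is.null(cmap$labels)) cmap$labels[left] <- 0L
  }
  # drop object rows dissolved pixel-wise in stage 2: the pixel layer is
  # authoritative for former line work
  if (!is.null(cmap$objects)) {
    dissolved <- cmap$objects$class_id == black
    if (any(dissolved)) cmap$objects <- cmap$objects[!dissolved, , drop = FALSE]
  }
  cmap$class_id <- cm
  cmap$provenance <- prov
  cmap
}

#' Apply manual override corrections
#'
#' The hand-editing step of a digitization run, captured as data: each entry
#' retargets an image object or a pixel box to a given class. Entries apply
#' in table order, so on overlap the later entry wins.
#'
#' @param cmap a [classified_map].
#' @param overrides data.frame with columns `target_type` (`"object"` or
#'   `"box"`), `target` (an object id, or `"col0,row0,col1,row1"` 0-based
#'   inclusive pixel bounds), `class_id` and free-text `reason`.
#' @return The edited [classified_map]; changed pixels carry provenance
#'   `override`.
#' @export
apply_overrides <- function(cmap, overrides) {
  stopifnot(inherits(cmap, "classified_map"))
  if (is.null(overrides) || nrow(overrides) == 0L) return(cmap)
  stopifnot(all(c("target_type", "target", "class_id") %in% names(overrides)))
  if (!all(overrides$class_id %in% cmap$legend$classes$class_id))
    stop("override classes absent from the legend: ",
         paste(setdiff(overrides$class_id, cmap$legend$classes$class_id),
               collapse = ", "))
  code <- provenance_code("override")
  for (i in seq_len(nrow(overrides))) {
    cls <- as.integer(overrides$class_id[i])
    if (overrides$target_type[i] == "object") {
      id <- as.integer(overrides$target[i])
      if (is.null(cmap$labels) || !any(cmap$labels == id))
        stop("override targets unknown object id ", id)
      px <- cmap$labels == id
      cmap$class_id[px] <- cls
      cmap$provenance[px] <- code
      if (!is.null(cmap$objects) && id %in% cmap$objects$id) {
        cmap$objects$class_id[cmap$objects$id == id] <- cls
        cmap$objects$provenance[cmap$objects$id == id] <- "override"
      }
    } else if (overrides$target_type[i] == "box") {
      v <- as.integer(strsplit(as.character(overrides$target[i]), ",")[[1]])
      if (length(v) != 4L || anyNA(v)) stop("malformed box target: ",
                                            overrides$target[i])
      cols <- (v[1]:v[3]) + 1L
      rows <- (v[2]:v[4]) + 1L
      cols <- cols[cols >= 1 & cols <= ncol(cmap$class_id)]
      rows <- rows[rows >= 1 & rows <= nrow(cmap$class_id)]
      cmap$class_id[rows, cols] <- cls
      cmap$provenance[rows, cols] <- code
    } else stop("unknown override target_type: ", overrides$target_type[i])
  }
  cmap
}

#' Fill missing units from a fallback map
#'
#' Where a map reports no data for whole units, a close-in-time companion map
#' can stand in: within the listed units, pixels that are nodata in the
#' primary map take the fallback map's class.
#'
#' @param primary,fallback [classified_map]s on the identical grid.
#' @param zones a [zone_layer].
#' @param unit_ids unit ids (present in `zones`) to fill.
#' @return The filled primary map; filled pixels carry provenance
#'   `fallback-map`.
#' @export
fill_missing_from <- function(primary, fallback, zones, unit_ids) {
  stopifnot(inherits(primary, "classified_map"),
            inherits(fallback, "classified_map"),
            inherits(zones, "zone_layer"))
  if (!isTRUE(all.equal(primary$geotransform, fallback$geotransform)) ||
      !all(dim(primary$class_id) == dim(fallback$class_id)))
    stop("primary and fallback maps are not on the same grid")
  if (length(unit_ids) == 0L) return(primary)
  missing_units <- setdiff(unit_ids, zones$units$unit_id)
  if (length(missing_units))
    stop("unit ids absent from the zone layer: ",
         paste(missing_units, collapse = ", "))
  uras <- rasterize_zones(zones, primary$geotransform, dim(primary$class_id))
  idx <- match(unit_ids, zones$units$unit_id)
  nd <- nodata_class(primary$legend)
  sel <- (uras %in% idx) & primary$class_id == nd &
    fallback$class_id != nodata_class(fallback$legend)
  sel <- matrix(sel, nrow(uras), ncol(uras))
  primary$class_id[sel] <- fallback$class_id[sel]
  primary$provenance[sel] <- provenance_code("fallback-map")
  primary
}
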