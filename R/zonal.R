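#' Zonal analysis parameters
#'
#' A unit's majority class is only trusted when it is clear: the top density
#' class must exceed the runner-up by more than `majority_margin` percentage
#' points (e.g. 45% vs 20% is a margin of exactly 25 points and fails a
#' strict > 25 test), and at least a `min_coverage` fraction of the unit's
#' official area must carry some density class at all — units with mostly
#' missing information are excluded rather than guessed.
#'
#' @param majority_margin percentage points (0-100).
#' @param min_coverage fraction of unit area (0-1).
#' @return An object of class `zonal_params`.
#' @export
zonal_params <- function(majority_margin = 25, min_coverage = 0.25) {
  stopifnot(majority_margin >= 0, majority_margin <= 100,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(majority_margin = majority_margin,
                 min_coverage = min_coverage), class = "zonal_params")
}

#' Class areas and percentages by zone unit
#'
#' Pixel-centre rule in an equal-area projection: a unit's class area is the
#' number of class pixels whose centres fall inside the unit times the pixel
#' ground area, in km^2. Percentages are relative to the unit's *official*
#' area (not to its classified area), so partially covered units show up as
#' low coverage rather than inflated percentages.
#'
#' @param cmap a [classified_map], georeferenced, equal-area CRS.
#' @param zones a [zone_layer] in the same CRS.
#' @return An object of class `zonal_table`: `areas` (long table `unit_id,
#'   state_id, class_id, area_km2, percent`), `units` (per-unit coverage and
#'   majority slots, filled by [assign_majority()]), `state_areas` and the
#'   legend.
#' @export
zonal_class_areas <- function(cmap, zones) {
  stopifnot(inherits(cmap, "classified_map"), inherits(zones, "zone_layer"))
  if (!is.null(cmap$crs) && !is.null(zones$crs) &&
      !identical(cmap$crs, zones$crs))
    stop(sprintf("CRS mismatch: map %s vs zones %s", cmap$crs, zones$crs))
  uras <- rasterize_zones(zones, cmap$geotransform, dim(cmap$class_id))
  px_km2 <- pixel_area(cmap) / 1e6
  lg <- cmap$legend
  dens <- density_classes(lg)

  inside <- uras > 0L
  tab <- table(unit = uras[inside], class = cmap$class_id[inside])
  areas <- as.data.frame(tab, stringsAsFactors = FALSE)
  areas <- areas[areas$Freq > 0, , drop = FALSE]
  ui <- as.integer(areas$unit)
  areas <- data.frame(unit_id = zones$units$unit_id[ui],
                      state_id = zones$units$state_id[ui],
                      class_id = as.integer(areas$class),
                      area_km2 = areas$Freq * px_km2)
  official <- zones$units$official_area_km2[match(areas$unit_id,
                                                  zones$units$unit_id)]
  areas$percent <- 100 * areas$area_km2 / official
  areas <- areas[order(areas$unit_id, areas$class_id), ]
  rownames(areas) <- NULL

  units <- zones$units[c("unit_id", "state_id", "official_area_km2")]
  dens_areas <- areas[areas$class_id %in% dens, , drop = FALSE]
  if (nrow(dens_areas)) {
    cov <- stats::aggregate(area_km2 ~ unit_id, dens_areas, sum)
    units$coverage <- cov$area_km2[match(units$unit_id, cov$unit_id)] /
      units$official_area_km2
    units$coverage[is.na(units$coverage)] <- 0
  } else {
    units$coverage <- 0
  }
  units$majority <- NA_integer_
  units$margin <- NA_real_
  units$valid <- NA

  if (nrow(areas)) {
    sa <- stats::aggregate(area_km2 ~ state_id + class_id, areas, sum)
    sa <- sa[order(sa$state_id, sa$class_id), ]
    rownames(sa) <- NULL
  } else {
    sa <- data.frame(state_id = character(), class_id = integer(),
                     area_km2 = numeric())
  }

  structure(list(areas = areas, units = units, state_areas = sa,
                 legend = lg, pixel_area_km2 = px_km2, params = NULL),
            class = "zonal_table")
}

#' @export
print.zonal_table <- function(x, ...) {
  cat(sprintf("<zonal_table> %d units, %d states%s\n", nrow(x$units),
              length(unique(x$units$state_id)),
              if (is.null(x$params)) " (majority not yet assigned)" else ""))
  invisible(x)
}

#' Assign majority classes under the clear-majority rule
#'
#' The majority class is the density class with the greatest percent area in
#' the unit. A unit is `valid` only when its coverage reaches `min_coverage`
#' AND the majority leads the next most abundant density class by strictly
#' more than `majority_margin` percentage points; only density classes
#' compete. Invalid units keep their percentages but are excluded from
#' change analysis.
#'
#' @param zt a [zonal_table][zonal_class_areas()].
#' @param params a [zonal_params].
#' @return The table with `majority`, `margin` and `valid` filled.
#' @export
assign_majority <- function(zt, params = zonal_params()) {
  stopifnot(inherits(zt, "zonal_table"))
  dens <- density_classes(zt$legend)
  u <- zt$units
  for (i in seq_len(nrow(u))) {
    a <- zt$areas[zt$areas$unit_id == u$unit_id[i] &
                    zt$areas$class_id %in% dens, , drop = FALSE]
    if (!nrow(a)) {
      u$majority[i] <- NA_integer_; u$margin[i] <- NA_real_
      u$valid[i] <- FALSE
      next
    }
    a <- a[order(-a$percent, a$class_id), ]
    u$majority[i] <- a$class_id[1]
    second <- if (nrow(a) >= 2) a$percent[2] else 0
    u$margin[i] <- a$percent[1] - second
    u$valid[i] <- u$coverage[i] >= params$min_coverage &&
      u$margin[i] > params$majority_margin
  }
  zt$units <- u
  zt$params <- params
  zt
}

#' Between-map change categories by unit
#'
#' Compares the majority classes of two majority-assigned zonal tables over
#' the same units. Only units valid in both maps receive a category:
#' `decreased`, `same`, `+1` or `>+1` by the difference of ordered density
#' class indices (legend order). Units valid in exactly one map are reported
#' with `valid_both = FALSE` and no category.
#'
#' @param a,b majority-assigned `zonal_table`s (earlier map first).
#' @param legend the shared [map_legend] (class ordering).
#' @return data.frame `unit_id, class_a, class_b, delta, category,
#'   valid_both`.
#' @export
change_classes <- function(a, b, legend) {
  stopifnot(inherits(a, "zonal_table"), inherits(b, "zonal_table"))
  if (is.null(a$params) || is.null(b$params))
    stop("both tables must be majority-assigned (run assign_majority first)")
  ua <- a$units; ub <- b$units
  extra_a <- setdiff(ua$unit_id, ub$unit_id)
  extra_b <- setdiff(ub$unit_id, ua$unit_id)
  if (length(extra_a) || length(extra_b))
    stop("unit id mismatch; only in first: [",
         paste(extra_a, collapse = ", "), "], only in second: [",
         paste(extra_b, collapse = ", "), "]")
  dens <- density_classes(legend)
  idx <- function(cls) match(cls, dens)
  m <- data.frame(unit_id = ua$unit_id,
                  class_a = ua$majority,
                  class_b = ub$majority[match(ua$unit_id, ub$unit_id)])
  va <- ua$valid
  vb <- ub$valid[match(ua$unit_id, ub$unit_id)]
  m$valid_both <- va & vb
  m$delta <- ifelse(m$valid_both, idx(m$class_b) - idx(m$class_a), NA_integer_)
  m$category <- NA_character_
  ok <- m$valid_both
  m$category[ok & m$delta < 0] <- "decreased"
  m$category[ok & m$delta == 0] <- "same"
  m$category[ok & m$delta == 1] <- "+1"
  m$category[ok & m$delta > 1] <- ">+1"
  m[c("unit_id", "class_a", "class_b", "delta", "category", "valid_both")]
}

#' Write a zonal table to CSV
#' @param zt a [zonal_table][zonal_class_areas()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_zonal_table <- function(zt, path) {
  a <- zt$areas
  u <- zt$units
  a$coverage <- u$coverage[match(a$unit_id, u$unit_id)]
  a$majority <- u$majority[match(a$unit_id, u$unit_id)]
  a$margin <- u$margin[match(a$unit_id, u$unit_id)]
  a$valid <- u$valid[match(a$unit_id, u$unit_id)]
  utils::write.csv(a, path, row.names = FALSE)
  invisible(path)
}
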