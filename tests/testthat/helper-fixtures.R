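# shared fixture builders; everything is generated in code

# flat-colour RGB image from a matrix of palette indices
paint_image <- function(idx, palette, geotransform = c(0, 1, 0, 0, 0, 1)) {
  a <- array(0, c(nrow(idx), ncol(idx), 3))
  for (b in 1:3) a[, , b] <- matrix(palette[idx, b], nrow(idx), ncol(idx))
  raster_image(a, geotransform)
}

# random 3-colour image used by the segmentation oracle tests
random_palette_image <- function(h, w, seed, jitter = 3) {
  set.seed(seed)
  pal <- matrix(sample(c(0, 128, 255), 9, replace = TRUE), 3)
  idx <- matrix(sample(1:3, h * w, replace = TRUE), h, w)
  img <- paint_image(idx, pal)
  a <- img$array + sample(-jitter:jitter, h * w * 3, replace = TRUE)
  raster_image(pmin(pmax(a, 0), 255))
}

# run the compiled fast/naive routes directly on a raster_image
segment_fast <- function(img, scale = 10, conn = 4L, w = c(1, 1, 1)) {
  d <- dim(img$array)
  matrix(mapreclaim:::cpp_mrs_segment(
    as.numeric(img$array[, , 1]), as.numeric(img$array[, , 2]),
    as.numeric(img$array[, , 3]), rep(FALSE, d[1] * d[2]),
    d[1], d[2], scale, w, conn), d[1], d[2])
}

segment_naive <- function(img, scale = 10, conn = 4L, w = c(1, 1, 1)) {
  d <- dim(img$array)
  matrix(mapreclaim:::cpp_mrs_segment_naive(
    as.numeric(img$array[, , 1]), as.numeric(img$array[, , 2]),
    as.numeric(img$array[, , 3]), rep(FALSE, d[1] * d[2]),
    d[1], d[2], scale, w, conn), d[1], d[2])
}

# minimal zonal_table for unit-level rule tests: one row per class percent
manual_zonal_table <- function(percents, official = 100, coverage = NULL,
                               legend = deer_density_legend()) {
  cls <- as.integer(names(percents))
  areas <- data.frame(unit_id = "U1", state_id = "S1", class_id = cls,
                      area_km2 = official * percents / 100,
                      percent = as.numeric(percents))
  cov <- if (is.null(coverage)) sum(percents) / 100 else coverage
  units <- data.frame(unit_id = "U1", state_id = "S1",
                      official_area_km2 = official, coverage = cov,
                      majority = NA_integer_, margin = NA_real_, valid = NA)
  sa <- stats::aggregate(area_km2 ~ state_id + class_id, areas, sum)
  structure(list(areas = areas, units = units, state_areas = sa,
                 legend = legend, pixel_area_km2 = 1, params = NULL),
            class = "zonal_table")
}

# square zone layer helper (metres)
square_zone <- function(x0, y0, side, unit_id = "U1", state_id = "S1",
                        official_area_km2 = NULL) {
  ring <- cbind(c(x0, x0 + side, x0 + side, x0),
                c(y0, y0, y0 + side, y0 + side))
  units <- data.frame(unit_id = unit_id, state_id = state_id)
  if (!is.null(official_area_km2)) units$official_area_km2 <- official_area_km2
  zone_layer(units, list(list(ring)))
}

expect_same_partition <- function(a, b) {
  # partitions are equal iff the label maps are identical after the
  # deterministic contiguous relabelling both routes apply
  expect_identical(as.integer(a), as.integer(b))
}
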