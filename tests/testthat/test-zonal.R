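test_that("class areas follow the pixel-centre rule", {
  lg <- deer_density_legend()
  gt <- c(500, 1000, 0, 9500, 0, -1000)   # 10x10 px of 1 km^2
  zones <- square_zone(0, 0, 10000, "U1", official_area_km2 = 100)
  cm <- classified_map(matrix(1L, 10, 10), lg, gt)
  zt <- zonal_class_areas(cm, zones)
  expect_equal(zt$areas$area_km2, 100)
  expect_equal(zt$areas$percent, 100)
  expect_equal(zt$units$coverage, 1)

  # half class, half nodata: 50% of official area, coverage 0.5
  half <- matrix(0L, 10, 10); half[1:5, ] <- 1L
  zt2 <- zonal_class_areas(classified_map(half, lg, gt), zones)
  a1 <- zt2$areas[zt2$areas$class_id == 1, ]
  expect_equal(a1$area_km2, 50)
  expect_equal(a1$percent, 50)
  expect_equal(zt2$units$coverage, 0.5)

  # zero-overlap unit: coverage 0, no error
  far <- square_zone(1e6, 1e6, 1000, "far")
  zt3 <- zonal_class_areas(cm, far)
  expect_equal(zt3$units$coverage, 0)

  cm_bad <- classified_map(matrix(1L, 10, 10), lg, gt, crs = "EPSG:4326")
  expect_error(zonal_class_areas(cm_bad, zones), "CRS mismatch")
})

test_that("zonal totals conserve whole-raster class areas", {
  spec <- synthetic_map_spec(n_units = 12, extent_km = c(20, 15),
                             resolution = 100, border_width = 0,
                             label_density = 0, blur_sigma = 0, noise_sd = 0,
                             seed = 91)
  sim <- simulate_map(spec)
  cm <- color_threshold_segment(sim$image, spec$legend, 30)
  zt <- zonal_class_areas(cm, sim$zones)
  raster_tot <- table(cm$class_id) * pixel_area(cm) / 1e6
  zonal_tot <- tapply(zt$areas$area_km2, zt$areas$class_id, sum)
  for (cl in names(zonal_tot))
    expect_equal(as.numeric(zonal_tot[cl]), as.numeric(raster_tot[cl]),
                 tolerance = 0.01)
})

test_that("the clear-majority margin rule is strict", {
  # 45% vs 20%: margin exactly 25 points fails a strict > 25 test
  zt <- manual_zonal_table(c("1" = 45, "2" = 20))
  out <- assign_majority(zt, zonal_params(majority_margin = 25))
  expect_equal(out$units$majority, 1L)
  expect_equal(out$units$margin, 25)
  expect_false(out$units$valid)
  # 45.1% vs 20%: margin 25.1 flips the unit to valid
  zt2 <- manual_zonal_table(c("1" = 45.1, "2" = 20))
  out2 <- assign_majority(zt2, zonal_params(majority_margin = 25))
  expect_true(out2$units$valid)

  # a single class fills the unit: margin 100, valid
  full <- assign_majority(manual_zonal_table(c("2" = 100)))
  expect_equal(full$units$majority, 2L)
  expect_equal(full$units$margin, 100)
  expect_true(full$units$valid)

  # clear majority but low coverage is still excluded
  lowcov <- assign_majority(manual_zonal_table(c("1" = 20), coverage = 0.2))
  expect_equal(lowcov$units$margin, 20)
  expect_false(lowcov$units$valid)
})

test_that("raising the margin never turns an invalid unit valid", {
  set.seed(95)
  for (i in 1:20) {
    p <- stats::runif(4, 0, 40)
    zt <- manual_zonal_table(stats::setNames(p, 1:4))
    valid <- vapply(c(5, 15, 25, 35, 60), function(m) {
      assign_majority(zt, zonal_params(majority_margin = m))$units$valid
    }, logical(1))
    expect_true(all(diff(as.integer(valid)) <= 0))
  }
})

test_that("change categories follow the ordered class index difference", {
  lg <- deer_density_legend()
  mk <- function(percent_by_unit) {
    areas <- do.call(rbind, lapply(names(percent_by_unit), function(u) {
      p <- percent_by_unit[[u]]
      data.frame(unit_id = u, state_id = "S1",
                 class_id = as.integer(names(p)), area_km2 = as.numeric(p),
                 percent = as.numeric(p))
    }))
    units <- data.frame(unit_id = names(percent_by_unit), state_id = "S1",
                        official_area_km2 = 100, coverage = 1,
                        majority = NA_integer_, margin = NA_real_, valid = NA)
    sa <- stats::aggregate(area_km2 ~ state_id + class_id, areas, sum)
    zt <- structure(list(areas = areas, units = units, state_areas = sa,
                         legend = lg, pixel_area_km2 = 1, params = NULL),
                    class = "zonal_table")
    assign_majority(zt)
  }
  a <- mk(list(U1 = c("1" = 90), U2 = c("1" = 90), U3 = c("2" = 90),
               U4 = c("4" = 90), U5 = c("1" = 40, "2" = 35)))
  b <- mk(list(U1 = c("1" = 90), U2 = c("3" = 90), U3 = c("3" = 90),
               U4 = c("2" = 90), U5 = c("1" = 90)))
  ch <- change_classes(a, b, lg)
  expect_equal(ch$category[ch$unit_id == "U1"], "same")
  expect_equal(ch$category[ch$unit_id == "U2"], ">+1")  # class 1 -> 3
  expect_equal(ch$category[ch$unit_id == "U3"], "+1")
  expect_equal(ch$category[ch$unit_id == "U4"], "decreased")
  expect_false(ch$valid_both[ch$unit_id == "U5"])  # unclear in map a
  expect_true(is.na(ch$category[ch$unit_id == "U5"]))

  # antisymmetry: swapping the maps reverses increases into decreases
  rev <- change_classes(b, a, lg)
  expect_equal(rev$category[rev$unit_id == "U1"], "same")
  expect_equal(rev$category[rev$unit_id == "U2"], "decreased")
  expect_equal(rev$category[rev$unit_id == "U4"], ">+1")  # class 2 -> 4

  b_missing <- mk(list(U1 = c("1" = 90)))
  expect_error(change_classes(a, b_missing, lg), "U2")
})
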