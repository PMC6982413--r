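test_that("free-class calibration solves the linear identity", {
  # hand case: areas {low 100, high 10}, v_high 17.4, T 274 -> 1.0
  areas <- data.frame(class_id = c(1L, 4L), area_km2 = c(100, 10))
  spec <- calibration_spec(target_total = 274, free_class = 1L,
                           fixed_values = c("4" = 17.4))
  expect_equal(calibrate_free_class(areas, spec), 1.0)

  # target exactly equal to the fixed contributions: free value 0
  spec0 <- calibration_spec(target_total = 174, free_class = 1L,
                            fixed_values = c("4" = 17.4))
  expect_equal(calibrate_free_class(areas, spec0), 0)

  # no free-class area: unsolvable; unreachable target: warning
  areas2 <- data.frame(class_id = 4L, area_km2 = 10)
  expect_error(calibrate_free_class(areas2, spec), "unsolvable")
  specn <- calibration_spec(target_total = 100, free_class = 1L,
                            fixed_values = c("4" = 17.4))
  expect_warning(calibrate_free_class(areas, specn), "negative")
  expect_error(calibration_spec(free_class = 4L,
                                fixed_values = c("4" = 17.4)), "free class")
})

test_that("calibration round-trips through population estimation", {
  lg <- deer_density_legend()
  set.seed(105)
  for (i in 1:10) {
    areas <- data.frame(unit_id = "U1", state_id = "S1", class_id = 1:4,
                        area_km2 = stats::runif(4, 10, 1000))
    areas$percent <- NA
    units <- data.frame(unit_id = "U1", state_id = "S1",
                        official_area_km2 = sum(areas$area_km2),
                        coverage = 1, majority = NA, margin = NA, valid = NA)
    zt <- structure(list(areas = areas, units = units,
                         state_areas = areas[c("state_id", "class_id",
                                               "area_km2")],
                         legend = lg, pixel_area_km2 = 1, params = NULL),
                    class = "zonal_table")
    target <- stats::runif(1, 1e4, 1e7)
    vals <- stats::setNames(stats::runif(3, 1, 20), 2:4)
    v <- calibrate_free_class(zt, calibration_spec(target, 1L, vals))
    lg2 <- lg
    lg2$classes$density[match(c(1:4), lg2$classes$class_id)] <-
      c(v, vals[["2"]], vals[["3"]], vals[["4"]])
    nat <- estimate_population(zt, lg2, level = "national")
    expect_equal(nat$population, target, tolerance = 1e-6)
  }
})

test_that("population estimation is linear and aggregates consistently", {
  lg <- deer_density_legend()
  set.seed(106)
  areas <- expand.grid(unit_id = sprintf("U%d", 1:6), class_id = 1:4)
  areas$state_id <- rep(c("S1", "S1", "S2", "S2", "S3", "S3"), 4)
  areas$area_km2 <- stats::runif(24, 5, 200)
  areas$percent <- NA
  units <- data.frame(unit_id = sprintf("U%d", 1:6),
                      state_id = c("S1", "S1", "S2", "S2", "S3", "S3"),
                      official_area_km2 = as.vector(
                        rowsum(areas$area_km2, areas$unit_id)),
                      coverage = 1, majority = NA, margin = NA, valid = NA)
  zt <- structure(list(areas = areas, units = units,
                       state_areas = stats::aggregate(
                         area_km2 ~ state_id + class_id, areas, sum),
                       legend = lg, pixel_area_km2 = 1, params = NULL),
                  class = "zonal_table")
  st <- estimate_population(zt, lg, "state")
  un <- estimate_population(zt, lg, "unit")
  nat <- estimate_population(zt, lg, "national")
  expect_equal(sum(st$population), nat$population)
  expect_equal(sum(un$population), nat$population)
  expect_equal(sum(st$presence_area_km2), nat$presence_area_km2)

  lg2 <- lg; lg2$classes$density <- lg$classes$density * 2
  expect_equal(estimate_population(zt, lg2, "national")$population,
               2 * nat$population)

  lgNA <- lg; lgNA$classes$density[lgNA$classes$class_id == 1] <- NA
  expect_error(estimate_population(zt, lgNA, "state"), "class\\(es\\): 1")
})

test_that("national presence density divides printed totals correctly", {
  expect_equal(national_presence_density(17148500, 4752100), 3.6)
  expect_equal(national_presence_density(29928700, 5561500), 5.4)
  expect_equal(national_presence_density(123.4, 123.4), 1.0)
  expect_error(national_presence_density(10, 0), "zero presence area")
})

test_that("comparison tables compute differences, quotients and MAE", {
  r <- data.frame(state = c("Alabama", "X"), estimate = c(1750000, 5))
  m <- data.frame(state = c("Alabama", "Y"), estimate = c(1313020, 7))
  cmp <- compare_estimates(r, m)
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$difference, 436980)
  expect_equal(cmp$quotient, 1.33)
  expect_equal(attr(cmp, "unmatched")$reported_only, "X")

  same <- data.frame(state = letters[1:4], estimate = c(10, 20, 30, 0))
  cs <- compare_estimates(same, same)
  expect_true(all(cs$difference == 0))
  expect_equal(cs$quotient[1:3], rep(1, 3))
  expect_true(is.na(cs$quotient[4]))   # zero map estimate: undefined
  expect_equal(attr(cs, "mae"), 0)
  expect_error(compare_estimates(r, data.frame(state = "Z", estimate = 1)),
               "in common")
})

test_that("annual statistics use the sample standard deviation", {
  ark <- annual_stats(c(1000000, 1000000, 750000, 750000))
  expect_equal(ark$mean, 875000)
  expect_equal(round(ark$sd), 144338)
  ky <- annual_stats(c(850000, 850000, 900000, 900000))
  expect_equal(ky$mean, 875000)
  expect_equal(round(ky$sd), 28868)
  expect_equal(annual_stats(rep(5, 4))$sd, 0)
  expect_equal(annual_stats(c(NA, 3))$n, 1L)
  expect_true(is.na(annual_stats(c(NA, 3))$sd))
  expect_error(annual_stats(NA_real_), "no values")
})

test_that("state counting respects the reporting precision", {
  t1 <- bundled_table("state_density")
  s <- data.frame(statewide_density = t1$density_2003)
  expect_equal(count_states_at_or_above(s, 9.8), 6L)
  expect_equal(count_states_at_or_above(s, 0),
               nrow(t1))  # every state rounds to >= 0
  expect_equal(count_states_at_or_above(s, 99), 0L)
  # a density of 9.7501 prints as 9.8 and must count
  expect_equal(count_states_at_or_above(
    data.frame(statewide_density = 9.7501), 9.8), 1L)
})
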