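small_spec <- function(seed, ...) {
  args <- list(n_units = 10L, extent_km = c(12, 8), resolution = 100,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_map_spec, args)
}

test_that("tessellation is deterministic and conserves the extent area", {
  sp <- small_spec(201)
  z1 <- generate_tessellation(sp)
  z2 <- generate_tessellation(sp)
  expect_identical(z1$geometry, z2$geometry)
  expect_identical(z1$units, z2$units)
  areas <- vapply(z1$geometry, polygon_area_m2, numeric(1))
  expect_true(all(areas > 0))
  expect_equal(sum(areas), 12 * 8 * 1e6, tolerance = 1e-6)

  one <- generate_tessellation(small_spec(202, n_units = 1L))
  expect_equal(one$units$official_area_km2, 96)
})

test_that("clean renders use palette colours exactly and record the truth", {
  sp <- small_spec(203, border_width = 0L, label_density = 0,
                   blur_sigma = 0, noise_sd = 0)
  z <- generate_tessellation(sp)
  r <- render_choropleth(z, sp)
  lg <- sp$legend
  pal <- lg$classes[lg$classes$role == "density", c("red", "green", "blue")]
  cols <- unique(cbind(as.vector(r$image$array[, , 1]),
                       as.vector(r$image$array[, , 2]),
                       as.vector(r$image$array[, , 3])))
  expect_true(all(apply(cols, 1, function(cc)
    any(cc[1] == pal$red & cc[2] == pal$green & cc[3] == pal$blue))))
  # truth equals the rendered classes when nothing is drawn on top
  cm <- color_threshold_segment(r$image, lg, 30)
  expect_identical(cm$class_id, r$truth$classes)
  # a degenerate class distribution paints a single class
  rp <- render_choropleth(z, small_spec(204, class_probs = c(1, 0, 0, 0),
                                        border_width = 0L, label_density = 0))
  expect_true(all(rp$truth$classes == 1L))
})

test_that("border ink roughly matches the geometric boundary length", {
  sp <- small_spec(205, border_width = 1L, label_density = 0,
                   blur_sigma = 0, noise_sd = 0)
  z <- generate_tessellation(sp)
  r <- render_choropleth(z, sp)
  black <- r$image$array[, , 1] == 0 & r$image$array[, , 2] == 0 &
    r$image$array[, , 3] == 0
  perimeter <- function(poly) sum(vapply(poly, function(ring) {
    ring <- rbind(ring, ring[1, , drop = FALSE])
    sum(sqrt(rowSums(diff(ring)^2)))
  }, numeric(1)))
  total_per <- sum(vapply(z$geometry, perimeter, numeric(1)))
  extent_per <- 2 * (12 + 8) * 1000
  # interior boundaries are shared by two cells; the stroke paints each once
  boundary_m <- (total_per - extent_per) / 2
  expect_equal(sum(black), boundary_m / sp$resolution, tolerance = 0.2)
})

test_that("degradation is seed-deterministic with the stated noise level", {
  sp <- small_spec(206)
  z <- generate_tessellation(sp)
  r <- render_choropleth(z, sp)
  d1 <- degrade(r$image, sp)
  d2 <- degrade(r$image, sp)
  expect_identical(d1$array, d2$array)
  expect_true(min(d1$array) >= 0 && max(d1$array) <= 255)

  # identity when both degradations are off
  sp0 <- small_spec(206, blur_sigma = 0, noise_sd = 0)
  expect_identical(degrade(r$image, sp0)$array, r$image$array)

  # pure noise: mean absolute change approx sd * sqrt(2/pi)
  spn <- small_spec(207, blur_sigma = 0, noise_sd = 4)
  zn <- generate_tessellation(spn)
  rn <- render_choropleth(zn, spn)
  # measure away from clipping (palette colours at 0/255 clip the noise)
  dn <- degrade(rn$image, spn)
  mid <- rn$image$array > 20 & rn$image$array < 235
  mad <- mean(abs(dn$array[mid] - rn$image$array[mid]))
  expect_equal(mad, 4 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("recovery scoring is exact on self-comparison and conserves counts", {
  sp <- small_spec(208)
  sim <- simulate_map(sp)
  perfect <- classified_map(sim$truth$classes, sp$legend,
                            sim$image$geotransform)
  ev <- evaluate_recovery(sim$truth, perfect)
  expect_equal(ev$pixel_accuracy, 1.0)
  expect_equal(ev$unit_majority_accuracy, 1.0)
  expect_true(all(diag(ev$confusion) == rowSums(ev$confusion)))

  # constant map on iid equiprobable classes scores near 1/4
  spi <- small_spec(209, n_units = 60L, extent_km = c(30, 20),
                    smoothing_iters = 0L)
  simi <- simulate_map(spi)
  const <- classified_map(matrix(1L, nrow(simi$truth$classes),
                                 ncol(simi$truth$classes)),
                          spi$legend, simi$image$geotransform)
  evc <- evaluate_recovery(simi$truth, const)
  expect_equal(evc$pixel_accuracy, 0.25, tolerance = 0.35)
  # confusion rows count truth pixels exactly
  expect_equal(as.numeric(rowSums(evc$confusion)),
               as.numeric(table(factor(simi$truth$classes,
                                       levels = sort(unique(c(simi$truth$classes,
                                                              1L)))))))
  wrong <- classified_map(matrix(1L, 2, 2), spi$legend)
  expect_error(evaluate_recovery(simi$truth, wrong), "same grid")
})
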