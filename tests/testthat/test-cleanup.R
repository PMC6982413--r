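# a classified map with a 3-pixel black speck inside a solid class-2 field
speck_setup <- function() {
  lg <- deer_density_legend()
  pal <- as.matrix(lg$classes[, c("red", "green", "blue")])
  idx <- matrix(3L, 8, 8)            # legend row 3 = class 2
  idx[4, 3:5] <- 6L                  # legend row 6 = black ink
  img <- paint_image(idx, pal)
  seg <- multiresolution_segment(img, segmentation_params(scale = 10))
  cls <- ifelse(seg$objects$mean_R < 60, 9L, 2L)
  cmap <- classified_map(matrix(cls[seg$labels], 8, 8), lg,
                         objects = data.frame(id = seg$objects$id,
                                              class_id = cls,
                                              provenance = "model"),
                         labels = seg$labels)
  list(legend = lg, seg = seg, cmap = cmap)
}

test_that("black detection uses per-band object means", {
  obj <- data.frame(id = 1:3, n = c(4, 4, 4),
                    mean_R = c(0, 200, 50), mean_G = c(0, 30, 61),
                    mean_B = c(0, 30, 20),
                    sd_R = 0, sd_G = 0, sd_B = 0)
  expect_equal(detect_black_objects(obj), 1L)
  expect_equal(detect_black_objects(obj, cleanup_params(black_max_channel = 61)),
               c(1L, 3L))
})

test_that("small black specks are absorbed into the enclosing class", {
  s <- speck_setup()
  out <- absorb_black_objects(s$cmap, s$seg)
  expect_true(all(out$class_id == 2L))
  expect_equal(sum(out$provenance == mapreclaim:::provenance_code("rule")), 3L)
})

test_that("absorption conserves pixels, removes all ink and is idempotent", {
  spec <- synthetic_map_spec(n_units = 8, extent_km = c(15, 10),
                             resolution = 100, seed = 81)
  sim <- simulate_map(spec)
  cm <- color_threshold_segment(sim$image, spec$legend, 30)
  n_black_before <- sum(cm$class_id == 9L)
  expect_gt(n_black_before, 0)
  out <- absorb_black_objects(cm, NULL)
  expect_equal(sum(out$class_id == 9L), 0L)
  expect_equal(length(out$class_id), length(cm$class_id))  # conservation
  again <- absorb_black_objects(out, NULL)
  expect_identical(again$class_id, out$class_id)

  # a map with no black pixels passes through unchanged
  clean <- out
  expect_identical(absorb_black_objects(clean, NULL)$class_id, out$class_id)
})

test_that("a thin border line is split between its sides", {
  lg <- deer_density_legend()
  cm <- matrix(1L, 9, 9); cm[, 6:9] <- 3L; cm[, 5] <- 9L
  cmap <- classified_map(cm, lg)
  out <- absorb_black_objects(cmap, NULL)
  expect_equal(sum(out$class_id == 9L), 0L)
  # each former border pixel joins a side; with one neighbour each the tie
  # goes to the lower class id
  expect_true(all(out$class_id[, 5] == 1L))
  expect_identical(out$class_id[, -5], cm[, -5])
})

test_that("overrides change exactly their targets, later entries winning", {
  s <- speck_setup()
  expect_identical(apply_overrides(s$cmap, NULL), s$cmap)

  black_id <- s$cmap$objects$id[s$cmap$objects$class_id == 9L][1]
  ov <- data.frame(target_type = "object", target = black_id,
                   class_id = 4L, reason = "test")
  out <- apply_overrides(s$cmap, ov)
  changed <- out$class_id != s$cmap$class_id
  expect_identical(which(changed), which(s$cmap$labels == black_id))
  expect_true(all(out$class_id[changed] == 4L))

  ov2 <- rbind(data.frame(target_type = "box", target = "0,0,3,3",
                          class_id = 1L, reason = "a"),
               data.frame(target_type = "box", target = "2,2,3,3",
                          class_id = 4L, reason = "b"))
  out2 <- apply_overrides(s$cmap, ov2)
  expect_true(all(out2$class_id[1:2, 1:4] == 1L))
  expect_true(all(out2$class_id[3:4, 3:4] == 4L))  # later entry wins

  bad <- data.frame(target_type = "object", target = 9999L,
                    class_id = 1L, reason = "x")
  expect_error(apply_overrides(s$cmap, bad), "9999")
})

test_that("fallback filling is confined to the listed nodata units", {
  lg <- deer_density_legend()
  gt <- c(500, 1000, 0, 9500, 0, -1000)   # 10x10 km at 1 km pixels
  za <- square_zone(0, 0, 5000, "A")
  zb <- square_zone(5000, 0, 5000, "B")
  zones <- zone_layer(rbind(za$units, zb$units), c(za$geometry, zb$geometry))
  primary <- classified_map(matrix(0L, 10, 10), lg, gt)
  fb <- classified_map(matrix(3L, 10, 10), lg, gt)

  expect_identical(fill_missing_from(primary, fb, zones, character(0)),
                   primary)
  out <- fill_missing_from(primary, fb, zones, "A")
  uras <- rasterize_zones(zones, gt, c(10, 10))
  expect_true(all(out$class_id[uras == 1] == 3L))
  expect_true(all(out$class_id[uras != 1] == 0L))
  expect_true(all(out$provenance[uras == 1] ==
                    mapreclaim:::provenance_code("fallback-map")))

  wrong_grid <- classified_map(matrix(3L, 9, 10), lg, gt)
  expect_error(fill_missing_from(primary, wrong_grid, zones, "A"),
               "same grid")
  expect_error(fill_missing_from(primary, fb, zones, "Z"), "absent")
})
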