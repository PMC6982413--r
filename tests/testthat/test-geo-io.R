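test_that("polynomial transform recovers known mappings exactly", {
  # identity on 3 points, order 1
  g <- data.frame(src_col = c(0, 10, 0), src_row = c(0, 0, 10))
  g$map_x <- g$src_col; g$map_y <- g$src_row
  t1 <- fit_polynomial_transform(g, 1)
  expect_equal(t1$coeffs_x, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(t1$coeffs_y, c(0, 0, 1), tolerance = 1e-12)
  expect_lt(t1$rms_residual, 1e-9)

  # known affine x' = 2 col + 10, y' = -3 row + 5 from 12 points
  set.seed(7)
  g <- data.frame(src_col = runif(12, 0, 100), src_row = runif(12, 0, 80))
  g$map_x <- 2 * g$src_col + 10
  g$map_y <- -3 * g$src_row + 5
  ta <- fit_polynomial_transform(g, 1)
  expect_equal(ta$coeffs_x, c(10, 2, 0), tolerance = 1e-9)
  expect_equal(ta$coeffs_y, c(5, 0, -3), tolerance = 1e-9)
  expect_lt(ta$rms_residual, 1e-8)

  # exact cubic through 10 points is reproduced (critically determined)
  set.seed(11)
  cx <- rnorm(10); cy <- rnorm(10)
  u <- runif(10, 0, 10); v <- runif(10, 0, 10)
  X <- mapreclaim:::poly_design(u, v, 3)
  g3 <- data.frame(src_col = u, src_row = v,
                   map_x = drop(X %*% cx), map_y = drop(X %*% cy))
  t3 <- fit_polynomial_transform(g3, 3)
  expect_lt(t3$rms_residual, 1e-6)
  expect_equal(t3$coeffs_x, cx, tolerance = 1e-6)
  expect_equal(t3$coeffs_y, cy, tolerance = 1e-6)
})

test_that("degenerate and undersized GCP sets are rejected", {
  g <- data.frame(src_col = c(0, 1), src_row = c(0, 0),
                  map_x = c(0, 1), map_y = c(0, 0))
  expect_error(fit_polynomial_transform(g, 1), "at least 3")
  # collinear points cannot determine an affine
  g <- data.frame(src_col = 0:4, src_row = 0:4, map_x = 0:4, map_y = 0:4)
  expect_error(fit_polynomial_transform(g, 1), "degenerate")
  g$map_x[1] <- NA
  expect_error(fit_polynomial_transform(g, 1), "finite")
})

test_that("nearest-neighbour warp preserves pixels under identity and shifts", {
  set.seed(3)
  a <- array(sample(0:255, 30 * 40 * 3, replace = TRUE), c(30, 40, 3))
  img <- raster_image(a)
  gid <- data.frame(src_col = c(0, 39, 0, 39), src_row = c(0, 0, 29, 29))
  gid$map_x <- gid$src_col; gid$map_y <- gid$src_row
  tid <- fit_polynomial_transform(gid, 1)
  w <- warp_image(img, tid, list(geotransform = c(0, 1, 0, 0, 0, 1),
                                 dim = c(30, 40)))
  expect_identical(w$array, a + 0)
  expect_false(any(w$nodata))

  # pure translation by +5 columns: content shifts, margin becomes nodata
  gtr <- gid; gtr$map_x <- gtr$src_col + 5
  ttr <- fit_polynomial_transform(gtr, 1)
  w2 <- warp_image(img, ttr, list(geotransform = c(0, 1, 0, 0, 0, 1),
                                  dim = c(30, 45)))
  expect_identical(w2$array[, 6:45, ], a + 0)
  expect_true(all(w2$nodata[, 1:5]))
})

test_that("warp then inverse-warp under a mild affine is near-identity", {
  set.seed(5)
  a <- array(sample(0:255, 40 * 60 * 3, replace = TRUE), c(40, 60, 3))
  img <- raster_image(a)
  g <- data.frame(src_col = c(0, 59, 0, 59, 30), src_row = c(0, 0, 39, 39, 20))
  g$map_x <- 1.003 * g$src_col + 0.002 * g$src_row + 12
  g$map_y <- -0.002 * g$src_col + 0.998 * g$src_row - 4
  tf <- fit_polynomial_transform(g, 1)
  og <- suggest_output_grid(tf, 60, 40)
  wf <- warp_image(img, tf, og)
  # reverse transform: warped pixel -> original pixel coordinates
  corners <- data.frame(col = c(0, og$dim[2] - 1, 0, og$dim[2] - 1),
                        row = c(0, 0, og$dim[1] - 1, og$dim[1] - 1))
  mp <- pixel_to_map(og$geotransform, corners$col, corners$row)
  src <- apply_transform(tf, mp$x, mp$y, inverse = TRUE)
  gb <- data.frame(src_col = corners$col, src_row = corners$row,
                   map_x = src$col, map_y = src$row)
  tb <- fit_polynomial_transform(gb, 1)
  back <- warp_image(wf, tb, list(geotransform = c(0, 1, 0, 0, 0, 1),
                                  dim = c(40, 60)))
  interior <- !back$nodata
  interior[c(1, 40), ] <- FALSE; interior[, c(1, 60)] <- FALSE
  match_frac <- mean(back$array[, , 1][interior] == a[, , 1][interior])
  expect_gte(match_frac, 0.99)
})

test_that("raster write/read round trip is bit exact, world file included", {
  set.seed(9)
  a <- array(sample(0:255, 12 * 15 * 3, replace = TRUE), c(12, 15, 3))
  gt <- c(500.5, 30, 0, 9999.5, 0, -30)
  img <- raster_image(a, gt)
  p <- file.path(tempdir(), "rt.png")
  write_raster(img, p)
  back <- read_raster(p)
  expect_identical(back$array, a + 0)
  expect_equal(back$geotransform, gt, tolerance = 1e-12)
  expect_true(back$georeferenced)

  # no world file: unit geotransform and a warning flag
  p2 <- file.path(tempdir(), "nowf.png")
  png::writePNG(a / 255, p2)
  expect_warning(bare <- read_raster(p2), "world file")
  expect_equal(bare$geotransform, c(0, 1, 0, 0, 0, 1))
  expect_false(bare$georeferenced)
})

test_that("integer rasters and GCP tables round trip through text files", {
  m <- matrix(sample(0:9, 35, replace = TRUE), 5, 7)
  storage.mode(m) <- "integer"
  p <- file.path(tempdir(), "labels.tsv")
  write_int_raster(m, p, geotransform = c(0, 2, 0, 10, 0, -2))
  back <- read_int_raster(p)
  expect_equal(attr(back, "geotransform"), c(0, 2, 0, 10, 0, -2))
  attr(back, "geotransform") <- NULL
  expect_identical(back, m)

  g <- data.frame(src_col = c(0, 5, 2), src_row = c(1, 3, 8),
                  map_x = c(100, 200, 150), map_y = c(7, 8, 9))
  pg <- file.path(tempdir(), "gcps.csv")
  utils::write.csv(g, pg, row.names = FALSE)
  expect_equal(read_gcps(pg), g)
})

test_that("zone layers round trip through GeoJSON with areas intact", {
  z1 <- square_zone(0, 0, 10000, "A", "S1")
  z2 <- square_zone(10000, 0, 10000, "B", "S1")
  z3 <- square_zone(0, 10000, 20000, "C", "S2")
  zones <- zone_layer(rbind(z1$units, z2$units, z3$units),
                      c(z1$geometry, z2$geometry, z3$geometry))
  expect_equal(zones$units$official_area_km2, c(100, 100, 400))
  p <- file.path(tempdir(), "zones.geojson")
  write_vector(zones, p)
  back <- read_zones(p)
  expect_equal(back$units$unit_id, c("A", "B", "C"))
  expect_equal(back$units$official_area_km2, c(100, 100, 400))
  expect_true(all(vapply(back$geometry, polygon_area_m2, numeric(1)) > 0))
})
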