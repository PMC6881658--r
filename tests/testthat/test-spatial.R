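test_that("IDW prediction is exact at sample locations", {
  w <- toy_wells()
  expect_equal(idw_predict(w$lon, w$lat, w), w$cf)
})

test_that("a single sample predicts its own value everywhere", {
  one <- data.frame(id = "a", lon = 0.3, lat = 0.7, cf = 12.5)
  expect_equal(idw_predict(c(-5, 0, 9), c(2, -3, 4), one), rep(12.5, 3))
})

test_that("equidistant samples average by symmetry", {
  two <- data.frame(id = c("a", "b"), lon = c(0, 2), lat = c(0, 0),
                    cf = c(10, 20))
  expect_equal(idw_predict(1, 0, two), 15)
  expect_equal(idw_predict(1, 5, two, idw_params(power = 3.7)), 15)
})

test_that("predictions are convex combinations of sample values", {
  set.seed(61)
  w <- generate_wells(synth_config(40, seed = 61))
  tx <- runif(30, 60.5, 60.9); ty <- runif(30, 27.0, 27.4)
  for (p in c(0.5, 1, 2, 6)) {
    pred <- idw_predict(tx, ty, w, idw_params(power = p))
    expect_true(all(pred >= min(w$cf) - 1e-12))
    expect_true(all(pred <= max(w$cf) + 1e-12))
  }
})

test_that("large powers approach the nearest-neighbour prediction", {
  set.seed(62)
  w <- generate_wells(synth_config(25, seed = 62))
  tx <- runif(12, 60.5, 60.9); ty <- runif(12, 27.0, 27.4)
  nn <- vapply(seq_along(tx), function(i) {
    d <- sqrt((w$lon - tx[i])^2 + (w$lat - ty[i])^2)
    w$cf[which.min(d)]
  }, numeric(1))
  pred <- idw_predict(tx, ty, w, idw_params(power = 200))
  expect_equal(pred, nn, tolerance = 1e-6)
})

test_that("grid interpolation is deterministic, bounded and shaped by the grid", {
  w <- generate_wells(synth_config(30, seed = 63))
  g <- grid_spec(c(60.5, 27.0, 60.9, 27.4), cell_size = 0.05)
  r1 <- interpolate_grid(w, g)
  r2 <- interpolate_grid(w, g)
  expect_identical(r1, r2)
  expect_equal(dim(r1$values), c(g$nrows, g$ncols))
  expect_true(all(r1$values >= min(w$cf) & r1$values <= max(w$cf)))

  # constant field in, constant raster out
  wc <- w; wc$cf <- 17.3
  rc <- interpolate_grid(wc, g)
  expect_true(all(abs(rc$values - 17.3) < 1e-12))

  # 1x1 grid
  g1 <- grid_spec(c(0, 0, 1, 1), cell_size = 1)
  r1x1 <- interpolate_grid(toy_wells(), g1)
  expect_equal(dim(r1x1$values), c(1, 1))
  expect_equal(r1x1$values[1, 1], 25)  # center equidistant from 4 corners
})

test_that("raster rows run north to south with correct cell centers", {
  w <- data.frame(id = c("s", "n"), lon = c(0.5, 0.5), lat = c(0.25, 0.75),
                  cf = c(10, 40))
  g <- grid_spec(c(0, 0, 1, 1), cell_size = 0.5)
  r <- interpolate_grid(w, g, idw_params(power = 2))
  # row 1 is the northern band: nearer the 40 mg/L well
  expect_true(all(r$values[1, ] > r$values[2, ]))
})

test_that("translation of wells and grid leaves the raster unchanged", {
  w <- generate_wells(synth_config(20, seed = 64))
  g <- grid_spec(c(60.5, 27.0, 60.9, 27.4), cell_size = 0.1)
  r <- interpolate_grid(w, g)
  w2 <- w; w2$lon <- w$lon + 3; w2$lat <- w$lat - 1.5
  g2 <- grid_spec(c(63.5, 25.5, 63.9, 25.9), cell_size = 0.1)
  r2 <- interpolate_grid(w2, g2)
  expect_equal(r$values, r2$values, tolerance = 1e-9)
})

test_that("search radius yields nodata and neighbor caps select the nearest", {
  w <- toy_wells()
  far <- idw_predict(10, 10, w, idw_params(search_radius = 1))
  expect_true(is.na(far))
  near <- idw_predict(0.1, 0.1, w, idw_params(max_neighbors = 1))
  expect_equal(near, 10)
})

test_that("samples lacking coordinates are excluded, duplicates averaged", {
  w <- rbind(toy_wells(),
             data.frame(id = "e", lon = NA_real_, lat = NA_real_, cf = 99))
  expect_warning(p <- idw_predict(0, 0, w), "without coordinates")
  expect_equal(p, 10)
  dup <- data.frame(id = c("a", "b"), lon = c(0, 0), lat = c(0, 0),
                    cf = c(10, 30))
  expect_warning(pd <- idw_predict(0, 0, dup), "averaged")
  expect_equal(pd, 20)
  no_geo <- data.frame(id = "a", cf = 1)
  expect_error(idw_predict(0, 0, no_geo), "coordinates")
})

test_that("exceedance masks are strict and propagate nodata", {
  w <- generate_wells(synth_config(30, seed = 65))
  g <- grid_spec(c(60.5, 27.0, 60.9, 27.4), cell_size = 0.05)
  r <- interpolate_grid(w, g)
  # survey-bounded values never exceed the 50 mg/L guideline
  m50 <- exceedance_mask(r, 50)
  expect_true(all(!m50$values))
  tiny <- exceedance_mask(r, 0.001)
  expect_true(all(tiny$values))

  r$values[1, 1] <- NA
  m <- exceedance_mask(r, 20)
  expect_true(is.na(m$values[1, 1]))
  expect_error(exceedance_mask(r, 0), "positive")
})

test_that("ESRI ASCII rasters round-trip through write and read", {
  w <- generate_wells(synth_config(15, seed = 66))
  g <- grid_spec(c(60.5, 27.0, 60.9, 27.4), cell_size = 0.1)
  r <- interpolate_grid(w, g)
  r$values[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(r, path)
  lines <- readLines(path)
  expect_match(lines[1], "^NCOLS 4$")
  expect_match(lines[2], "^NROWS 4$")
  expect_match(lines[6], "^NODATA_VALUE")
  back <- read_esri_ascii(path)
  expect_equal(back$values, r$values, tolerance = 1e-8)
  expect_equal(back$grid$bbox, r$grid$bbox, tolerance = 1e-10)
})

test_that("well GeoJSON carries point geometry and concentration", {
  path <- withr::local_tempfile(fileext = ".geojson")
  write_wells_geojson(toy_wells(), path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 4)
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$type, "Point")
  expect_equal(unlist(f1$geometry$coordinates), c(0, 0))
  expect_equal(f1$properties$no3_mg_l, 10)
})
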