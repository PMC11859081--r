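test_that("ESRI ASCII header fields and nodata masking are honored", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 4", "nrows 3", "xllcorner 100", "yllcorner 20",
               "cellsize 0.25", "NODATA_value -9999",
               "1 2 3 4", "5 -9999 7 8", "9 10 11 12"), path)
  lyr <- read_raster(path)
  expect_equal(lyr$grid$n_cols, 4L)
  expect_equal(lyr$grid$n_rows, 3L)
  expect_equal(lyr$grid$cell_size, 0.25)
  expect_equal(sum(lyr$mask), 11)
  expect_true(is.na(lyr$values[2, 2]))
  # row 1 is the top (north) row
  expect_equal(lyr$values[1, ], c(1, 2, 3, 4))
})

test_that("a 2x2 grid with one nodata value has 3 valid cells", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 2", "-9999 4"), path)
  expect_equal(sum(read_raster(path)$mask), 3)
})

test_that("write then read is the identity on values, mask and grid", {
  stack <- small_world()
  lyr <- stack$layers[[1]]
  lyr$values[5, 7] <- NA
  lyr$mask[5, 7] <- FALSE
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(lyr, path)
  back <- read_raster(path, name = lyr$name)
  expect_equal(back$values, lyr$values, tolerance = 1e-10)
  expect_identical(back$mask, lyr$mask)
  expect_equal(back$grid[c("n_rows", "n_cols", "x_min", "y_min", "cell_size")],
               lyr$grid[c("n_rows", "n_cols", "x_min", "y_min", "cell_size")])
})

test_that("malformed headers and unsupported formats raise informative errors", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols x", "nrows 2"), path)
  expect_error(read_raster(path), "ncols")
  writeLines(c("ncols 2", "cellsize 1", "1 2"), path)
  expect_error(read_raster(path), "nrows")
  expect_error(read_raster(path, format = "geotiff"), "not supported")
})

test_that("assemble_stack enforces exact grid equality and intersects masks", {
  g <- tiny_grid(1, 3, cell_size = 0.25)
  a <- env_layer("a", g, matrix(c(1, 2, NA), 1))
  b <- env_layer("b", g, matrix(c(NA, 5, 6), 1))
  st <- assemble_stack(list(a, b))
  expect_equal(as.vector(st$mask), c(FALSE, TRUE, FALSE))
  expect_equal(names(st$layers), c("a", "b"))

  g2 <- grid_spec(1, 3, 100, 20, 0.2500001)
  c_ <- env_layer("c", g2, matrix(1:3, 1))
  expect_error(assemble_stack(list(a, c_)), "cell_size")
  # idempotent and order preserving
  st2 <- assemble_stack(st$layers)
  expect_identical(names(st2$layers), names(st$layers))
  expect_identical(st2$mask, st$mask)
})

test_that("cell areas follow the spherical-zone closed form", {
  g <- grid_spec(360, 10, 0, -45, 0.25)
  # top row spans lat 44.75-45; find rows spanning 0-0.25 and 60-60.25
  # row r spans [y_top - r*s, y_top - (r-1)*s]; y_top = 45
  r_eq <- 180   # spans 0 to 0.25
  expect_equal(cell_area_km2(g, r_eq), 772.766574, tolerance = 1e-6)
  g2 <- grid_spec(4, 4, 0, 60, 0.25)
  expect_equal(cell_area_km2(g2, 4), 384.923481, tolerance = 1e-6)
  # mirror rows at +/- phi have equal area
  g3 <- grid_spec(8, 2, 0, -1, 0.25)
  expect_equal(cell_area_km2(g3, 1), cell_area_km2(g3, 8))
  expect_error(cell_area_km2(g3, 9), "out of range")
  # decreasing toward the pole
  gp <- grid_spec(10, 1, 0, 50, 1)
  expect_true(all(diff(cell_area_km2(gp, 1:10)) > 0))
})

test_that("global 1-degree grid areas close to the sphere surface", {
  g <- grid_spec(180, 360, -180, -90, 1)
  total <- sum(cell_area_km2(g, 1:180)) * 360
  expect_equal(total, 4 * pi * 6371^2, tolerance = 1e-4)
})

test_that("cell centers and point location follow the half-open convention", {
  g <- tiny_grid(2, 2, cell_size = 1, x_min = 0, y_min = 0)
  cent <- grid_centers(g)
  expect_equal(cent$lon, c(0.5, 1.5, 0.5, 1.5))
  expect_equal(cent$lat, c(1.5, 1.5, 0.5, 0.5))
  loc <- locate_cells(g, c(0, 0.999, 1.0, 2.0, -0.1), c(2, 1.001, 0.5, 0.5, 1))
  expect_equal(loc$row, c(1L, 1L, 2L, NA, NA))
  expect_equal(loc$col, c(1L, 1L, 2L, NA, NA))
})
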