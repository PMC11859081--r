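test_that("priority areas require co-occurring moderate-or-better habitat", {
  g <- tiny_grid(2, 2, cell_size = 1, x_min = 0, y_min = 0)
  mk <- function(v) classify_suitability(as_suit_map(matrix(v, 2, 2), g))
  # per-cell classes, cell order (1,1),(2,1),(1,2),(2,2) column-major:
  sp1 <- mk(c(0.9, 0.05, 0.5, 0.5))    # classes 3,0,2,2
  sp2 <- mk(c(0.1, 0.05, 0.5, 0.9))    # classes 0,0,2,3
  prio <- priority_areas(list(sp1, sp2), min_species = 2)
  expect_equal(as.vector(prio), c(FALSE, FALSE, TRUE, TRUE))
  # one species alone is not enough at min_species = 2
  expect_false(priority_areas(list(sp1, sp2), 2)[1, 1])
  # monotone: raising min_species never grows the mask
  p1 <- priority_areas(list(sp1, sp2), 1)
  expect_true(all(prio <= p1))
  # all species high everywhere -> everything priority
  all3 <- replicate(3, mk(rep(0.9, 4)), simplify = FALSE)
  expect_true(all(priority_areas(all3, 2)))
})

test_that("gap analysis reports the unprotected share of priority area", {
  g <- tiny_grid(2, 5, cell_size = 0.25, x_min = 0, y_min = 0)
  prio <- matrix(TRUE, 2, 5)
  pa <- matrix(FALSE, 2, 5)
  pa[1, 1:3] <- TRUE
  # cells in one row share identical area; protect 3 of 10 near-equal cells
  rep <- gap_analysis(prio, pa, g)
  expect_equal(rep$percent_unprotected,
               100 * (1 - rep$protected_overlap / rep$priority_area))
  expect_equal(round(rep$percent_unprotected, 1), 70, tolerance = 0.01)
  # full protection -> 0 percent unprotected
  full <- gap_analysis(prio, matrix(TRUE, 2, 5), g)
  expect_equal(full$percent_unprotected, 0)
  expect_error(gap_analysis(matrix(FALSE, 2, 5), pa, g), "empty")
})

test_that("the printed case-study gap figures are reproduced by the identity", {
  hv <- reference_table("headline")
  v <- setNames(hv$value, hv$quantity)
  pct <- 100 * (1 - v[["protected_overlap_1e4km2"]] / v[["priority_area_1e4km2"]])
  expect_equal(round(pct, 2), 96.84)
})

test_that("suitable centroids are area-weighted cell-center means", {
  g <- tiny_grid(1, 1, cell_size = 0.5, x_min = 10, y_min = 40)
  one <- suitable_centroid(as_suit_map(matrix(0.8, 1, 1), g))
  expect_equal(one$lon, 10.25)
  expect_equal(one$lat, 40.25)

  # symmetric mask about a meridian -> centroid on the meridian
  g2 <- tiny_grid(2, 3, cell_size = 1, x_min = 0, y_min = 0)
  m <- matrix(0.5, 2, 3)
  cen <- suitable_centroid(as_suit_map(m, g2))
  expect_equal(cen$lon, 1.5)

  # area weighting pulls the centroid equatorward
  g3 <- grid_spec(61, 1, 0, 0, 1)
  v <- matrix(0, 61, 1); v[1, 1] <- 0.9; v[61, 1] <- 0.9  # lat 60.5 and 0.5
  cen3 <- suitable_centroid(as_suit_map(v, g3))
  expect_lt(cen3$lat, 30.5)
  expect_error(suitable_centroid(as_suit_map(matrix(0.1, 1, 1), g)), "threshold")
})

test_that("centroid shifts are haversine distances on the 6371-km sphere", {
  same <- centroid_shift(c(100, 30), c(100, 30))
  expect_equal(same$distance_km, 0)
  one_deg <- centroid_shift(c(0, 0), c(0, 1))
  expect_equal(one_deg$distance_km, pi * 6371 / 180, tolerance = 1e-6)
  expect_equal(one_deg$bearing_deg, 0)
  # symmetry of distance and the triangle inequality
  p <- list(c(100, 20), c(103, 24), c(98, 27))
  d12 <- centroid_shift(p[[1]], p[[2]])$distance_km
  d21 <- centroid_shift(p[[2]], p[[1]])$distance_km
  d23 <- centroid_shift(p[[2]], p[[3]])$distance_km
  d13 <- centroid_shift(p[[1]], p[[3]])$distance_km
  expect_equal(d12, d21)
  expect_lte(d13, d12 + d23 + 1e-9)
})

test_that("printed case-study centroid steps are reproduced within 3 percent", {
  d1 <- centroid_shift(c(115.26, 27.46), c(114.23, 27.40))$distance_km
  expect_lt(abs(d1 - 103.66) / 103.66, 0.03)
  d2 <- centroid_shift(c(115.08, 27.53), c(114.99, 26.96))$distance_km
  expect_lt(abs(d2 - 64.70) / 64.70, 0.03)
})

test_that("centroid tracks chain consecutive periods", {
  b <- small_fit_bundle()
  cur <- predict(b$fit, b$stack)
  fut <- list(
    "S-2050" = project_future(b$fit, make_future_stack(b$stack,
      scenario_delta("S-2050", shift = c(temp = 1)))),
    "S-2070" = project_future(b$fit, make_future_stack(b$stack,
      scenario_delta("S-2070", shift = c(temp = 2)))))
  tk <- centroid_track(cur, fut, scenario = "S")
  expect_equal(nrow(tk), 3)
  expect_true(is.na(tk$distance_km[1]))
  expect_true(all(tk$distance_km[-1] >= 0))
  # step 2 distance equals the shift between the reported centroids
  d <- centroid_shift(c(tk$lon[2], tk$lat[2]), c(tk$lon[3], tk$lat[3]))
  expect_equal(tk$distance_km[3], d$distance_km)
})
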