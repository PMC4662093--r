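# Buffer summaries: clipped road sums, areal weighting, land-use
# proportions, emission aggregation — each against an independent oracle.

test_that("road sums clip at the buffer and apply the weightings", {
  r <- 300
  s <- one_site(0, 0)
  # one straight road through the center: diameter chord of length 2r
  roads <- road_layer(list(rbind(c(-5000, 0), c(5000, 0))),
                      "district_road", 4, 60, FALSE)
  len <- buffer_road_sum(s, r, roads, "ALL", "length")$value
  expect_equal(len, 2 * r / 1000)
  # lanes x width weighting is multiplicative: 2r * 4 lanes * 3 m in 1000 m^2
  wt <- width_table(data.frame(is_highway = FALSE, speed_min = 0,
                               speed_max = 200, is_urban = FALSE,
                               width_m = 3))
  lxw <- buffer_road_sum(s, r, roads, "ALL", "length_x_lanes_x_width",
                         width_table = wt)$value
  expect_equal(lxw, 2 * r * 4 * 3 / 1000)
  expect_equal(buffer_road_sum(s, r, roads, "ALL", "length_x_lanes")$value,
               2 * r * 4 / 1000)
  # empty intersection is 0, not missing
  far <- buffer_road_sum(one_site(1e6, 1e6), r, roads, "ALL", "length")$value
  expect_identical(far, 0)
  # class selection: no MR1 in this network
  expect_identical(buffer_road_sum(s, r, roads, "MR1", "length")$value, 0)
})

test_that("clipped road lengths match the fine-subdivision oracle", {
  set.seed(314)
  for (k in 1:20) {
    cx <- stats::runif(1, -50, 50)
    cy <- stats::runif(1, -50, 50)
    r <- stats::runif(1, 40, 150)
    line <- matrix(stats::runif(8, -200, 200), 4, 2)  # 3-segment polyline
    roads <- road_layer(list(line), "district_road", 2, 60, FALSE)
    got <- buffer_road_sum(one_site(cx, cy), r, roads, "ALL",
                           "length")$value * 1000
    want <- oracle_length_in_disc(line, cx, cy, r, step = 0.01)
    expect_equal(got, want, tolerance = max(0.005, 0.05 / max(want, 1)))
  }
})

test_that("areal weighting implements the area-fraction sum", {
  # buffer entirely inside one polygon: value = count * area ratio
  zone <- polygon_layer(list(t_rect(-1000, -1000, 1000, 1000)),
                        attrs = data.frame(pop = 100), layer_kind = "census")
  r <- 200
  got <- areal_weighted_sum(one_site(0, 0), r, zone, "pop")$value
  expect_equal(got, 100 * pi * r^2 / 4e6, tolerance = 2e-4)
  # polygon entirely inside the buffer contributes exactly its count
  small <- polygon_layer(list(t_rect(-10, -10, 10, 10)),
                         attrs = data.frame(pop = 100), layer_kind = "census")
  expect_equal(areal_weighted_sum(one_site(0, 0), 200, small, "pop")$value,
               100, tolerance = 1e-9)
  # a polygon merely touching the buffer contributes nothing
  touch <- polygon_layer(list(t_rect(200, -10, 300, 10)),
                         attrs = data.frame(pop = 50), layer_kind = "census")
  expect_equal(areal_weighted_sum(one_site(0, 0), 200, touch, "pop")$value, 0)
  expect_error(areal_weighted_sum(one_site(0, 0), 200, zone, "households"),
               "not found")
})

test_that("areal weighting agrees with the Monte-Carlo oracle", {
  # two half-plane polygons with counts 60/40, buffer centered on the split
  bounds <- list(c(-1000, -1000, 0, 1000), c(0, -1000, 1000, 1000))
  zones <- polygon_layer(lapply(bounds, function(b) do.call(t_rect, as.list(b))),
                         attrs = data.frame(pop = c(60, 40)),
                         layer_kind = "census")
  set.seed(99)
  r <- 250
  mc <- oracle_mc_areal(0, 0, r, bounds, c(60, 40), n = 2e5)
  got <- areal_weighted_sum(one_site(0, 0), r, zones, "pop")$value
  expect_lt(abs(got - mc$est), 3 * mc$se + 1e-9)
  # closed form for this symmetric case: (60 + 40)/2 * pi r^2 / 2e6 each side
  expect_equal(got, (60 + 40) * pi * r^2 / (2 * 2e6), tolerance = 2e-4)
})

test_that("land-use proportions are correct fractions of the buffer", {
  lc <- polygon_layer(list(t_rect(-1000, -1000, 0, 1000),
                           t_rect(0, -1000, 1000, 1000)),
                      attrs = data.frame(class_code = c("forest",
                                                        "residential")),
                      layer_kind = "landcover")
  # fully inside the residential part
  expect_equal(land_use_proportion(one_site(500, 0), 100, lc,
                                   "residential")$value, 1.0,
               tolerance = 1e-9)
  # half-plane split through the buffer center
  expect_equal(land_use_proportion(one_site(0, 0), 300, lc, "forest")$value,
               0.5, tolerance = 1e-9)
  # absent class yields 0
  expect_equal(land_use_proportion(one_site(0, 0), 300, lc, "wetland")$value,
               0)
  # proportions over a tessellating mosaic sum to 1
  tot <- land_use_proportion(one_site(0, 0), 300, lc, "forest")$value +
    land_use_proportion(one_site(0, 0), 300, lc, "residential")$value
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("emission cells become tiling polygons with summed sources", {
  tab <- emission_grid_table(data.frame(
    corner_x = c(0, 0, 0, 1000), corner_y = c(0, 0, 0, 0),
    source = c("point", "line", "area", "point"),
    pollutant = "NOx", estimate = c(2, 3, 5, 7)))
  lay <- emission_cells_to_polygons(tab)
  expect_equal(nrow(lay$attrs), 2L)
  expect_equal(lay$attrs$NOx, c(10, 7))
  # bottom-left corner convention
  expect_equal(sort(lay$geoms[[1]][[1]][, 1]), c(0, 0, 1000, 1000))
  expect_equal(sort(lay$geoms[[1]][[1]][, 2]), c(0, 0, 1000, 1000))
  # adjacent cells share an edge with zero overlap
  clip <- geocov:::regular_ngon(1000, 500, 400)
  a1 <- geocov:::clip_polygon_convex_area(lay$geoms[[1]], clip)
  a2 <- geocov:::clip_polygon_convex_area(lay$geoms[[2]], clip)
  expect_equal(a1 + a2, geocov:::ring_area_signed(clip), tolerance = 1e-9)

  # single emitting cell fully inside the buffer contributes exactly itself
  one <- emission_buffer_sum(one_site(500, 500), 3000, lay, "NOx")$value
  expect_equal(one, 17, tolerance = 1e-9)
  expect_error(emission_buffer_sum(one_site(0, 0), 3000, lay, "PM10"),
               "unknown pollutant")
})

test_that("uniform emission field recovers c * pi r^2 / cell_area", {
  cells <- expand.grid(corner_x = seq(-5000, 4000, 1000),
                       corner_y = seq(-5000, 4000, 1000))
  tab <- emission_grid_table(data.frame(
    corner_x = rep(cells$corner_x, 3), corner_y = rep(cells$corner_y, 3),
    source = rep(c("point", "line", "area"), each = nrow(cells)),
    pollutant = "PM10", estimate = 4))
  lay <- emission_cells_to_polygons(tab)
  got <- emission_buffer_sum(one_site(0, 0), 3000, lay, "PM10")$value
  expect_equal(got, 12 * pi * 3000^2 / 1e6, tolerance = 2e-4)
  # all-zero field
  tab0 <- emission_grid_table(data.frame(corner_x = 0, corner_y = 0,
                                         source = "point", pollutant = "CO",
                                         estimate = 0))
  expect_equal(emission_buffer_sum(one_site(500, 500), 3000,
                                   emission_cells_to_polygons(tab0),
                                   "CO")$value, 0)
})

test_that("buffer values are monotone in radius and conserve totals", {
  set.seed(21)
  zones <- polygon_layer(
    lapply(0:3, function(i) t_rect(i * 500 - 1000, -1000, (i + 1) * 500 - 1000,
                                   1000)),
    attrs = data.frame(pop = stats::runif(4, 0, 100)), layer_kind = "census")
  roads <- tiny_roads()
  radii <- c(25, 50, 100, 300, 500, 1000)
  s <- one_site(-123, 77)
  pops <- vapply(radii, function(r) {
    areal_weighted_sum(s, r, zones, "pop")$value
  }, numeric(1))
  lens <- vapply(radii, function(r) {
    buffer_road_sum(s, r, roads, "ALL", "length")$value
  }, numeric(1))
  expect_true(all(diff(pops) >= -1e-12))
  expect_true(all(diff(lens) >= -1e-12))

  # conservation: buffers tiling the layer recover the attribute total is a
  # property of the weights: full cover of every polygon -> sum of weights 1
  big <- areal_weighted_sum(one_site(0, 0), 5000, zones, "pop")$value
  expect_equal(big, sum(zones$attrs$pop), tolerance = 1e-9)
})
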