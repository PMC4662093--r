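# Domain types, validation, joins and plain-text I/O round trips.

test_that("type constructors enforce their invariants", {
  expect_error(monitoring_sites(c("a", "a"), 1:2, 1:2), "duplicate site_id")
  expect_error(monitoring_sites("a", NaN, 1), "finite")
  expect_error(road_layer(list(matrix(c(0, 0), 1, 2)), "district_road",
                          2, 60, FALSE), "fewer than 2 vertices")
  expect_error(road_layer(list(rbind(c(0, 0), c(1, 1))), "footpath",
                          2, 60, FALSE), "unknown road_type")
  expect_error(road_layer(list(rbind(c(0, 0), c(1, 1))), "district_road",
                          0, 60, FALSE), "lanes")
  # zero-area polygon rejected with the offending feature id
  expect_error(
    polygon_layer(list(t_rect(0, 0, 1, 1),
                       list(rbind(c(5, 5), c(6, 5), c(7, 5)))),
                  attrs = data.frame(feature_id = c("ok", "degenerate"))),
    "degenerate")
  expect_error(
    polygon_layer(list(t_rect(0, 0, 1, 1)),
                  attrs = data.frame(pop = -3), layer_kind = "census"),
    "negative census attribute")
  expect_error(point_layer(data.frame(x = 1, y = 2), "port"),
               "vessels_per_year")
  expect_error(
    emission_grid_table(data.frame(corner_x = c(0, 0), corner_y = c(0, 0),
                                   source = "point", pollutant = "NOx",
                                   estimate = 1)),
    "duplicate")
  expect_error(ndvi_stack(as.Date("2010-01-05"),
                          list(raster_grid(0, 0, 100, matrix(300, 2, 2)))),
               "outside declared range")
})

test_that("join_table_to_layer is a validated 1:1 join", {
  lay <- polygon_layer(list(t_rect(0, 0, 1, 1), t_rect(1, 0, 2, 1),
                            t_rect(2, 0, 3, 1)),
                       attrs = data.frame(jip = c("a", "b", "c")),
                       layer_kind = "census")
  tab <- data.frame(jip = c("a", "b", "c"), pop = c(10, 20, 30))
  out <- join_table_to_layer(lay, tab, "jip")
  expect_equal(out$attrs$pop, c(10, 20, 30))

  expect_warning(out2 <- join_table_to_layer(lay, tab[1:2, ], "jip"),
                 "unmatched")
  expect_equal(out2$attrs$pop, c(10, 20, NA))
  expect_equal(length(out2$geoms), 3L)

  expect_error(join_table_to_layer(lay, rbind(tab, tab[1, ]), "jip"),
               "duplicate key")
  expect_error(
    join_table_to_layer(lay, data.frame(jip = "zz", pop = 1), "jip"),
    "no rows matched")
  expect_error(join_table_to_layer(lay, tab, "nokey"), "nokey")
})

test_that("vector layers round-trip through WKT CSV to 1e-6 m", {
  lay <- polygon_layer(list(t_rect(100.123456, 200.654321, 300, 400),
                            t_rect(300, 200, 500.5, 400.25)),
                       attrs = data.frame(pop = c(5, 7.25)),
                       layer_kind = "census")
  f <- withr::local_tempfile(fileext = ".csv")
  write_vector_layer(lay, f, crs = "Custom TM (meters)")
  back <- load_vector_layer(f, "census")
  expect_equal(length(back$geoms), 2L)
  expect_equal(back$attrs$pop, lay$attrs$pop)
  expect_lt(max(abs(back$geoms[[1L]][[1L]] - lay$geoms[[1L]][[1L]])), 1e-6)
  expect_equal(back$areas, lay$areas, tolerance = 1e-9)

  roads <- tiny_roads()
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_vector_layer(roads, f2)
  back2 <- load_vector_layer(f2, "road")
  expect_equal(back2$attrs, roads$attrs)
  expect_equal(back2$geoms, roads$geoms)

  ports <- point_layer(data.frame(x = c(1.5, 2), y = c(3, 4.000001),
                                  vessels_per_year = c(20000, 100)), "port")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_vector_layer(ports, f3)
  back3 <- load_vector_layer(f3, "port")
  expect_equal(back3$x, ports$x)
  expect_equal(back3$vessels_per_year, ports$vessels_per_year)
})

test_that("loading rejects geographic CRS and missing schema columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# crs: EPSG:4326",
               '"wkt","pop"',
               '"POLYGON ((0 0, 1 0, 1 1, 0 1, 0 0))",3'), f)
  expect_error(load_vector_layer(f, "census"), "reproject")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"wkt","road_type","speed_limit","is_highway"',
               '"LINESTRING (0 0, 1 0)","district_road",60,FALSE'), f2)
  expect_error(load_vector_layer(f2, "road"), "lanes")
})

test_that("ASCII-grid raster I/O preserves orientation, values and nodata", {
  m <- matrix(as.numeric(1:12), nrow = 3, ncol = 4)  # row 1 = bottom
  m[2, 3] <- NA
  r <- raster_grid(100, 200, 30, m)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  back <- read_ascii_grid(f)
  expect_equal(back$origin_x, 100)
  expect_equal(back$origin_y, 200)
  expect_equal(back$cell_size, 30)
  expect_equal(back$values, r$values)
  # bottom-left cell value sits at the site just above the origin
  s <- one_site(101, 201)
  expect_equal(extract_cell_value(s, back), m[1, 1])
})

test_that("width table and emission table readers validate schema", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(is_highway = FALSE, speed_min = 0,
                              speed_max = 200, is_urban = FALSE,
                              width_m = 3.5), f, row.names = FALSE)
  wt <- read_width_table(f)
  expect_s3_class(wt, "width_table")
  expect_error(width_table(data.frame(is_highway = TRUE)), "schema error")
  expect_error(
    emission_grid_table(data.frame(corner_x = 0, corner_y = 0,
                                   source = "point", pollutant = "ozone",
                                   estimate = 1)),
    "pollutant")
})
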