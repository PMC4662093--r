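# Nearest distances, road classification, width lookup, port filtering and
# border-line derivation.

test_that("nearest_distance handles perpendicular feet, containment, ties", {
  s <- one_site(5, 3)
  d <- nearest_distance(s, list(seg = rbind(c(0, 0), c(10, 0))), "road")
  expect_equal(d$distance, 3)
  expect_equal(d$nearest_feature_id, "seg")

  # site lying on a feature
  expect_equal(nearest_distance(one_site(5, 0),
                                list(rbind(c(0, 0), c(10, 0))))$distance, 0)
  # inside a polygon -> 0; outside -> distance to boundary
  poly <- t_rect(0, 0, 10, 10)
  expect_equal(nearest_distance(one_site(5, 5), list(poly))$distance, 0)
  expect_equal(nearest_distance(one_site(15, 5), list(poly))$distance, 5)

  # equidistant features: lowest feature id wins
  tie <- nearest_distance(one_site(0, 0),
                          list(b = rbind(c(3, -10), c(3, 10)),
                               a = rbind(c(-3, -10), c(-3, 10))))
  expect_equal(tie$nearest_feature_id, "a")

  expect_warning(empty <- nearest_distance(s, list(), "nothing"),
                 "empty feature collection")
  expect_true(is.na(empty$distance))
  expect_true(is.na(empty$nearest_feature_id))
})

test_that("nearest_distance matches 1 cm densification on random segments", {
  set.seed(42)
  lines <- lapply(1:100, function(i) {
    a <- stats::runif(2, 0, 200)
    matrix(a + c(0, 0, stats::runif(2, -60, 60)), 2, 2, byrow = TRUE)
  })
  for (k in 1:5) {
    px <- stats::runif(1, 0, 200)
    py <- stats::runif(1, 0, 200)
    got <- nearest_distance(one_site(px, py), lines)$distance
    expect_equal(got, oracle_densified_dist(px, py, lines), tolerance = 0.01)
  }
})

test_that("distance is invariant under rigid motion and scales linearly", {
  set.seed(7)
  lines <- lapply(1:20, function(i) matrix(stats::runif(4, 0, 1000), 2, 2))
  px <- 321.5
  py <- 567.8
  d0 <- nearest_distance(one_site(px, py), lines)$distance
  # translation
  dt <- nearest_distance(one_site(px + 1e4, py - 2e4),
                         lapply(lines, function(l) {
                           sweep(l, 2, c(1e4, -2e4), `+`)
                         }))$distance
  expect_equal(dt, d0, tolerance = 1e-9)
  # rotation about an arbitrary center
  rot <- function(m) geocov:::rotate_coords(m, 37, 100, 200)
  dr <- nearest_distance(one_site(rot(cbind(px, py))[1], rot(cbind(px, py))[2]),
                         lapply(lines, rot))$distance
  expect_equal(dr, d0, tolerance = 1e-6)
  # uniform scaling
  ds <- nearest_distance(one_site(px * 3, py * 3),
                         lapply(lines, function(l) l * 3))$distance
  expect_equal(ds, 3 * d0, tolerance = 1e-9)
  # adding features never increases the minimum
  more <- c(lines, list(rbind(c(px + 1, py), c(px + 2, py))))
  expect_lte(nearest_distance(one_site(px, py), more)$distance, d0)
})

test_that("road classes follow the MR1/MR2 definitions", {
  expect_setequal(classify_road("national_highway", 4), c("ALL", "MR1", "MR2"))
  expect_setequal(classify_road("metro_city_highway", 2),
                  c("ALL", "MR1", "MR2"))
  # strictly more than six lanes qualifies a local road for MR2 only
  expect_setequal(classify_road("district_road", 8), c("ALL", "MR2"))
  expect_setequal(classify_road("district_road", 6), "ALL")
  expect_setequal(classify_road("district_road", 2), "ALL")
  # nesting invariant on random segments
  set.seed(11)
  roads <- road_layer(replicate(50, rbind(c(0, 0), c(1, 1)), simplify = FALSE),
                      road_type = sample(geocov:::ROAD_TYPES, 50, TRUE),
                      lanes = sample(1:10, 50, TRUE),
                      speed_limit = 60, is_highway = FALSE)
  mem <- road_class_membership(roads)
  expect_true(all(!mem[, "MR1"] | mem[, "MR2"]))  # MR1 subset of MR2
  expect_true(all(mem[, "ALL"]))                  # MR2 subset of ALL
})

test_that("urban classification is intersection-based, touching included", {
  urb <- polygon_layer(list(t_rect(0, 0, 100, 100)),
                       layer_kind = "urbanized_area")
  roads <- road_layer(
    list(rbind(c(10, 10), c(90, 90)),      # wholly inside
         rbind(c(50, 50), c(150, 50)),     # crossing the edge
         rbind(c(100, 20), c(160, 20)),    # touching the boundary only
         rbind(c(1100, 0), c(1200, 0))),   # 1 km away
    road_type = "district_road", lanes = 2, speed_limit = 60,
    is_highway = FALSE)
  expect_equal(classify_urban(roads, urb), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("width lookup uses half-open speed bands and flags gaps", {
  wt <- width_table(data.frame(
    is_highway = c(TRUE, FALSE, FALSE),
    speed_min = c(80, 0, 0), speed_max = c(120, 80, 80),
    is_urban = c(FALSE, TRUE, FALSE), width_m = c(3.6, 3.0, 3.25)))
  roads <- road_layer(list(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0), c(1, 0))),
                      road_type = c("national_highway", "district_road"),
                      lanes = c(4, 2), speed_limit = c(100, 60),
                      is_highway = c(TRUE, FALSE))
  expect_equal(assign_width(roads, c(FALSE, TRUE), wt), c(3.6, 3.0))
  expect_equal(assign_width(roads, c(FALSE, FALSE), wt)[2], 3.25)
  fast <- road_layer(list(rbind(c(0, 0), c(1, 0))), "district_road", 2, 200,
                     FALSE)
  expect_error(assign_width(fast, FALSE, wt), "does not cover")
  # shipped default covers every plausible combination
  dflt <- default_width_table()
  for (sl in c(1, 59.9, 60, 79.9, 80, 199))
    for (hw in c(TRUE, FALSE))
      for (ur in c(TRUE, FALSE)) {
        r1 <- road_layer(list(rbind(c(0, 0), c(1, 0))),
                         if (hw) "national_highway" else "district_road",
                         2, sl, hw)
        expect_gt(assign_width(r1, ur, dflt), 0)
      }
})

test_that("major-port filter is strict and monotone in the threshold", {
  ports <- point_layer(data.frame(x = 1:3, y = 1:3,
                                  vessels_per_year = c(9000, 10000, 10001)),
                       "port")
  expect_equal(nrow(filter_major_ports(ports, 10000)), 1L)
  expect_equal(filter_major_ports(ports, 10000)$vessels_per_year, 10001)
  expect_equal(nrow(filter_major_ports(ports[0, ], 10000)), 0L)
  # mirrored on synthetic counts: 10 of 31 ports exceed the threshold
  set.seed(5)
  v31 <- c(stats::runif(10, 10001, 60000), stats::runif(21, 0, 9999))
  p31 <- point_layer(data.frame(x = stats::runif(31), y = stats::runif(31),
                                vessels_per_year = sample(v31)), "port")
  expect_equal(nrow(filter_major_ports(p31, 10000)), 10L)
  # monotone non-increasing in threshold
  sizes <- vapply(c(0, 5000, 10000, 20000, 1e6),
                  function(th) nrow(filter_major_ports(p31, th)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("border derivation dissolves a tessellation and keeps the north", {
  # unit square as 4 quadrants; fraction 0.25 -> exactly the top edge y = 1
  quads <- polygon_layer(list(t_rect(0, 0, .5, .5), t_rect(.5, 0, 1, .5),
                              t_rect(0, .5, .5, 1), t_rect(.5, .5, 1, 1)),
                         layer_kind = "admin_district")
  segs <- derive_border_line(quads, 0.25)
  expect_gt(length(segs), 0)
  total <- sum(vapply(segs, function(s) geocov:::polyline_length(s),
                      numeric(1)))
  expect_equal(total, 1.0)
  expect_true(all(vapply(segs, function(s) all(s[, 2] == 1), logical(1))))

  # single rectangle: its own top portion
  one <- polygon_layer(list(t_rect(0, 0, 2, 1)), layer_kind = "admin_district")
  segs1 <- derive_border_line(one, 0.5)
  ys <- unlist(lapply(segs1, function(s) s[, 2]))
  expect_true(all(ys >= 0.5))

  # two disjoint islands: larger one used, with a warning
  islands <- polygon_layer(list(t_rect(0, 0, 10, 10), t_rect(100, 0, 101, 1)),
                           layer_kind = "admin_district")
  expect_warning(segs2 <- derive_border_line(islands, 0.25), "largest-area")
  xs <- unlist(lapply(segs2, function(s) s[, 1]))
  expect_true(all(xs <= 10))
})

test_that("network totals and shares reproduce printed-percentage arithmetic", {
  roads <- road_layer(
    list(rbind(c(0, 0), c(2000, 0)),          # MR1, 2 km
         rbind(c(0, 0), c(0, 1000)),          # MR2-only via lanes, 1 km
         rbind(c(0, 0), c(3000, 4000))),      # plain, 5 km
    road_type = c("national_highway", "district_road", "district_road"),
    lanes = c(4, 8, 2), speed_limit = c(100, 60, 60),
    is_highway = c(TRUE, FALSE, FALSE))
  tot <- road_network_totals(roads)
  expect_equal(unname(tot), c(8, 2, 3))
  sh <- road_class_share(tot)
  expect_equal(unname(sh), c(25, 37.5))
  expect_error(road_class_share(c(ALL = 0, MR1 = 0, MR2 = 0)), "positive")
})
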