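# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the implementation's geometry path:
# - distances are checked against densified-vertex brute force;
# - clipped road lengths against fine midpoint subdivision;
# - areal weights / land-use areas against Monte-Carlo point sampling, with
#   polygon membership decided by plain coordinate comparison on axis-aligned
#   rectangles (no shared polygon code).

# rectangle polygon helper (single CCW ring)
t_rect <- function(x0, y0, x1, y1) {
  list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

one_site <- function(x, y, id = "s1") monitoring_sites(id, x, y)

# brute-force min distance: densify every segment at `step` and take the
# minimum point-to-point distance
oracle_densified_dist <- function(px, py, lines, step = 0.01) {
  best <- Inf
  for (line in lines) {
    for (i in seq_len(nrow(line) - 1L)) {
      a <- line[i, ]
      b <- line[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      d2 <- (a[1L] + t * (b[1L] - a[1L]) - px)^2 +
            (a[2L] + t * (b[2L] - a[2L]) - py)^2
      best <- min(best, sqrt(min(d2)))
    }
  }
  best
}

# clipped-length oracle: subdivide at `step`, count midpoints inside the disc
oracle_length_in_disc <- function(line, cx, cy, r, step = 0.01) {
  total <- 0
  for (i in seq_len(nrow(line) - 1L)) {
    a <- line[i, ]
    b <- line[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    n <- max(1L, ceiling(len / step))
    tm <- (seq_len(n) - 0.5) / n
    mx <- a[1L] + tm * (b[1L] - a[1L])
    my <- a[2L] + tm * (b[2L] - a[2L])
    total <- total + sum((mx - cx)^2 + (my - cy)^2 <= r * r) * len / n
  }
  total
}

# membership of points in an axis-aligned rectangle given as its bounds;
# half-open on the max edges to make rect tessellations partition exactly
in_rect <- function(px, py, b) {
  px >= b[1L] & px < b[3L] & py >= b[2L] & py < b[4L]
}

# Monte-Carlo areal-weighted sum over a list of rectangles:
# rect_bounds = list of c(x0, y0, x1, y1); values = attribute per rectangle.
# Samples uniformly over the same regular-polygon buffer the implementation
# is specified to use (deciding membership by closed-form polar geometry,
# not by the package's clipping code), so the comparison isolates the
# areal-weighting computation from the documented ~1e-4 disc-polygon
# approximation. Returns estimate and its standard error.
oracle_mc_areal <- function(cx, cy, r, rect_bounds, values, n = 1e5,
                            ngon = 256L) {
  u <- stats::runif(n)
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(u)
  # boundary radius of the inscribed regular ngon at polar angle th:
  # apothem / cos(angle to the nearest edge normal)
  sector <- 2 * pi / ngon
  r_b <- r * cos(pi / ngon) / cos((th %% sector) - pi / ngon)
  keep <- rr <= r_b
  px <- (cx + rr * cos(th))[keep]
  py <- (cy + rr * sin(th))[keep]
  m <- sum(keep)
  f <- numeric(m)
  for (j in seq_along(rect_bounds)) {
    b <- rect_bounds[[j]]
    area_j <- (b[3L] - b[1L]) * (b[4L] - b[2L])
    f <- f + in_rect(px, py, b) * values[j] / area_j
  }
  a_ngon <- 0.5 * ngon * r^2 * sin(sector)
  list(est = a_ngon * mean(f), se = a_ngon * stats::sd(f) / sqrt(m))
}

# a tiny deterministic road layer: one horizontal road through (0, 0) and a
# diagonal national highway
tiny_roads <- function() {
  road_layer(list(rbind(c(-1000, 0), c(1000, 0)),
                  rbind(c(-500, -500), c(500, 500))),
             road_type = c("district_road", "national_highway"),
             lanes = c(2L, 4L), speed_limit = c(60, 100),
             is_highway = c(FALSE, TRUE))
}
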