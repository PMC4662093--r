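# Internal planar-geometry primitives. All coordinates are projected meters.
#
# Geometry representations used throughout the package:
#   point    - numeric length-2 vector c(x, y)
#   polyline - numeric matrix (n >= 2) x 2
#   ring     - numeric matrix (n >= 3) x 2, implicitly closed (no repeated
#              closing vertex); exterior rings CCW, hole rings CW
#   polygon  - list of rings, first = exterior, rest = holes

#' @keywords internal
ring_area_signed <- function(ring) {
  x <- ring[, 1L]
  y <- ring[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# total area of a polygon (list of rings); relies on hole rings being CW
polygon_area <- function(poly) {
  sum(vapply(poly, ring_area_signed, numeric(1)))
}

# drop a repeated closing vertex; orient exterior CCW and holes CW
normalize_polygon <- function(rings) {
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    n <- nrow(r)
    if (n > 1L && all(r[1L, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    r
  })
  lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    a <- ring_area_signed(r)
    want_ccw <- (i == 1L)
    if ((a < 0) == want_ccw) r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
    r
  })
}

# even-odd point-in-ring test, vectorized over points
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# even-odd across all rings, so holes are excluded
point_in_polygon <- function(px, py, poly) {
  inside <- logical(length(px))
  for (ring in poly) inside <- xor(inside, point_in_ring(px, py, ring))
  inside
}

# distances from one point to many segments, vectorized over segments
dist_point_segments <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  t <- ((px - x1) * dx + (py - y1) * dy) / ifelse(l2 == 0, 1, l2)
  t <- pmin(1, pmax(0, ifelse(l2 == 0, 0, t)))
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

dist_point_polyline <- function(px, py, line) {
  n <- nrow(line)
  if (n == 1L) return(sqrt((line[1L, 1L] - px)^2 + (line[1L, 2L] - py)^2))
  i <- seq_len(n - 1L)
  min(dist_point_segments(px, py, line[i, 1L], line[i, 2L],
                          line[i + 1L, 1L], line[i + 1L, 2L]))
}

# 0 inside (holes excluded), else distance to nearest ring edge
dist_point_polygon <- function(px, py, poly) {
  if (point_in_polygon(px, py, poly)) return(0)
  min(vapply(poly, function(r) {
    dist_point_polyline(px, py, rbind(r, r[1L, , drop = FALSE]))
  }, numeric(1)))
}

# minimum distance between two segments (0 if they intersect or touch)
dist_segment_segment <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- o(cx, cy, dx, dy, ax, ay)
  d2 <- o(cx, cy, dx, dy, bx, by)
  d3 <- o(ax, ay, bx, by, cx, cy)
  d4 <- o(ax, ay, bx, by, dx, dy)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(dist_point_segments(ax, ay, cx, cy, dx, dy),
      dist_point_segments(bx, by, cx, cy, dx, dy),
      dist_point_segments(cx, cy, ax, ay, bx, by),
      dist_point_segments(dx, dy, ax, ay, bx, by))
}

# does a polyline intersect a polygon (touching counts)?
polyline_intersects_polygon <- function(line, poly, tol = 1e-9) {
  if (any(point_in_polygon(line[, 1L], line[, 2L], poly))) return(TRUE)
  n <- nrow(line)
  for (ring in poly) {
    rc <- rbind(ring, ring[1L, , drop = FALSE])
    for (i in seq_len(n - 1L)) {
      for (j in seq_len(nrow(rc) - 1L)) {
        d <- dist_segment_segment(line[i, 1L], line[i, 2L],
                                  line[i + 1L, 1L], line[i + 1L, 2L],
                                  rc[j, 1L], rc[j, 2L],
                                  rc[j + 1L, 1L], rc[j + 1L, 2L])
        if (d <= tol) return(TRUE)
      }
    }
  }
  FALSE
}

polyline_length <- function(line) {
  n <- nrow(line)
  if (n < 2L) return(0)
  sum(sqrt(diff(line[, 1L])^2 + diff(line[, 2L])^2))
}

# length of the portion of segment (a, b) inside the disc of radius r at c
segment_length_in_circle <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1
  dy <- y2 - y1
  a <- dx * dx + dy * dy
  fx <- x1 - cx
  fy <- y1 - cy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  out <- numeric(length(x1))
  ok <- a > 0 & disc > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
    t2 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
    out[ok] <- pmax(0, t2 - t1) * sqrt(a[ok])
  }
  out
}

polyline_length_in_circle <- function(line, cx, cy, r) {
  n <- nrow(line)
  if (n < 2L) return(0)
  i <- seq_len(n - 1L)
  sum(segment_length_in_circle(line[i, 1L], line[i, 2L],
                               line[i + 1L, 1L], line[i + 1L, 2L], cx, cy, r))
}

# Sutherland-Hodgman clip of one ring against the half-plane left of (a -> b)
clip_ring_halfplane <- function(ring, ax, ay, bx, by) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  ex <- bx - ax
  ey <- by - ay
  side <- ex * (ring[, 2L] - ay) - ey * (ring[, 1L] - ax)
  if (all(side >= 0)) return(ring)
  out_x <- numeric(0)
  out_y <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    si <- side[i]
    sj <- side[j]
    if (si >= 0) {
      if (sj < 0) {
        t <- sj / (sj - si)
        out_x <- c(out_x, ring[j, 1L] + t * (ring[i, 1L] - ring[j, 1L]))
        out_y <- c(out_y, ring[j, 2L] + t * (ring[i, 2L] - ring[j, 2L]))
      }
      out_x <- c(out_x, ring[i, 1L])
      out_y <- c(out_y, ring[i, 2L])
    } else if (sj >= 0) {
      t <- sj / (sj - si)
      out_x <- c(out_x, ring[j, 1L] + t * (ring[i, 1L] - ring[j, 1L]))
      out_y <- c(out_y, ring[j, 2L] + t * (ring[i, 2L] - ring[j, 2L]))
    }
    j <- i
  }
  cbind(out_x, out_y, deparse.level = 0)
}

# clip a ring against a convex CCW ring; traversal orientation is preserved,
# so signed areas of clipped exterior/hole rings still sum correctly
clip_ring_convex <- function(ring, clip) {
  m <- nrow(clip)
  j <- m
  for (i in seq_len(m)) {
    ring <- clip_ring_halfplane(ring, clip[j, 1L], clip[j, 2L],
                                clip[i, 1L], clip[i, 2L])
    if (nrow(ring) == 0L) break
    j <- i
  }
  ring
}

# area of polygon-with-holes intersected with a convex CCW clip ring
clip_polygon_convex_area <- function(poly, clip) {
  sum(vapply(poly, function(r) {
    cr <- clip_ring_convex(r, clip)
    if (nrow(cr) < 3L) 0 else ring_area_signed(cr)
  }, numeric(1)))
}

ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1L]), ymin = min(ring[, 2L]),
    xmax = max(ring[, 1L]), ymax = max(ring[, 2L]))
}

polygon_bbox <- function(poly) ring_bbox(poly[[1L]])

bbox_overlaps_disc <- function(bb, cx, cy, r) {
  dx <- pmax(0, pmax(bb[["xmin"]] - cx, cx - bb[["xmax"]]))
  dy <- pmax(0, pmax(bb[["ymin"]] - cy, cy - bb[["ymax"]]))
  dx * dx + dy * dy <= r * r
}

# regular CCW n-gon inscribed in the circle of radius r; the standard
# polygonal approximation of a buffer disc (area deficit ~0.01% at n = 256)
regular_ngon <- function(cx, cy, r, n = 256L) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(theta), cy + r * sin(theta), deparse.level = 0)
}

rotate_coords <- function(m, angle_deg, ox = 0, oy = 0) {
  a <- angle_deg * pi / 180
  ca <- cos(a)
  sa <- sin(a)
  x <- m[, 1L] - ox
  y <- m[, 2L] - oy
  cbind(ox + ca * x - sa * y, oy + sa * x + ca * y, deparse.level = 0)
}
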