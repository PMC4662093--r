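# Nearest-feature distances and road classification: major-road classes
# (MR1/MR2), urban/non-urban assignment, width lookup, port filtering, and
# derivation of the northern border line from administrative polygons.

# normalize any supported layer/geometry list to list(geoms=, ids=)
feature_geoms <- function(features) {
  if (inherits(features, "geocov_roads"))
    return(list(geoms = features$geoms, ids = features$attrs$feature_id))
  if (inherits(features, "geocov_polygons"))
    return(list(geoms = features$geoms, ids = features$attrs$feature_id))
  if (inherits(features, "geocov_points")) {
    pts <- lapply(seq_len(nrow(features)), function(i) {
      c(features$x[i], features$y[i])
    })
    return(list(geoms = pts, ids = features$feature_id))
  }
  if (is.list(features)) {
    ids <- names(features)
    if (is.null(ids)) ids <- paste0("f", seq_along(features))
    return(list(geoms = features, ids = ids))
  }
  stop("unsupported feature collection", call. = FALSE)
}

dist_point_geometry <- function(px, py, g) {
  if (is.numeric(g) && !is.matrix(g))  # bare point
    return(sqrt((g[1L] - px)^2 + (g[2L] - py)^2))
  if (is.matrix(g)) return(dist_point_polyline(px, py, g))
  if (is.list(g)) return(dist_point_polygon(px, py, g))
  stop("unsupported geometry", call. = FALSE)
}

#' Distance to the nearest feature
#'
#' Minimum planar Euclidean distance from each site to a feature collection:
#' distance to a polyline includes segment interiors; distance to a polygon
#' is 0 for sites inside it, else the distance to its boundary. Ties between
#' equidistant features break to the lowest feature id, so output is
#' deterministic. An empty collection yields `NA` distances with a warning
#' (never a fabricated large value).
#'
#' @param sites a [monitoring_sites()] table.
#' @param features a [road_layer()], [point_layer()], [polygon_layer()] or a
#'   plain (optionally named) list of geometries: length-2 points, polyline
#'   matrices, or polygons (lists of ring matrices).
#' @param target label naming the feature class (stored in the result).
#' @return data frame with columns `site_id`, `target`, `distance`
#'   (meters), `nearest_feature_id`.
#' @examples
#' s <- monitoring_sites("a", 5, 3)
#' nearest_distance(s, list(seg = rbind(c(0, 0), c(10, 0))), "road")
#' @export
nearest_distance <- function(sites, features, target = "features") {
  fg <- feature_geoms(features)
  out <- data.frame(site_id = sites$site_id, target = target,
                    distance = NA_real_,
                    nearest_feature_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(fg$geoms) == 0L) {
    warning("empty feature collection for target '", target,
            "'; distances set to NA", call. = FALSE)
    return(out)
  }
  ord <- order(fg$ids)
  geoms <- fg$geoms[ord]
  ids <- fg$ids[ord]
  for (i in seq_len(nrow(sites))) {
    d <- vapply(geoms, function(g) {
      dist_point_geometry(sites$x[i], sites$y[i], g)
    }, numeric(1))
    k <- which.min(d)  # first minimum = lowest id after sorting
    out$distance[i] <- d[k]
    out$nearest_feature_id[i] <- ids[k]
  }
  out
}

#' Road class membership
#'
#' Every segment belongs to `ALL`; `MR1` membership is by road type; `MR2`
#' includes all of MR1 plus roads with strictly more lanes than the scheme's
#' threshold — so MR1 is always a subset of MR2, and MR2 of ALL.
#'
#' `classify_road()` returns the class set of a single segment;
#' `road_class_membership()` the logical membership matrix of a whole layer.
#'
#' @param road_type,lanes attributes of one segment.
#' @param scheme a [road_class_scheme()].
#' @return `classify_road()`: character vector, subset of
#'   `c("ALL", "MR1", "MR2")`; `road_class_membership()`: n x 3 logical matrix.
#' @examples
#' classify_road("national_highway", 4)
#' classify_road("district_road", 8)
#' @export
classify_road <- function(road_type, lanes, scheme = road_class_scheme()) {
  mr1 <- road_type %in% scheme$mr1_types
  mr2 <- mr1 || lanes > scheme$mr2_lane_threshold
  c("ALL", if (mr1) "MR1", if (mr2) "MR2")
}

#' @rdname classify_road
#' @param roads a [road_layer()].
#' @export
road_class_membership <- function(roads, scheme = road_class_scheme()) {
  mr1 <- roads$attrs$road_type %in% scheme$mr1_types
  mr2 <- mr1 | roads$attrs$lanes > scheme$mr2_lane_threshold
  cbind(ALL = rep(TRUE, nrow(roads$attrs)), MR1 = mr1, MR2 = mr2)
}

#' Urban/non-urban road assignment
#'
#' A segment is urban iff its geometry intersects any urbanized-area polygon;
#' touching the polygon boundary counts as intersecting.
#'
#' @param roads a [road_layer()].
#' @param urbanized a [polygon_layer()] of urbanized areas.
#' @return logical vector, one flag per segment.
#' @export
classify_urban <- function(roads, urbanized) {
  stopifnot(inherits(urbanized, "geocov_polygons"))
  vapply(roads$geoms, function(line) {
    for (poly in urbanized$geoms)
      if (polyline_intersects_polygon(line, poly)) return(TRUE)
    FALSE
  }, logical(1))
}

#' Per-lane width lookup
#'
#' Looks up the width for each segment by (highway flag, speed band
#' containing the speed limit, urban flag); bands are half-open
#' `[speed_min, speed_max)`. An attribute combination not covered by the
#' table is a configuration error naming the combination.
#'
#' @param roads a [road_layer()].
#' @param is_urban logical vector from [classify_urban()] (recycled).
#' @param table a [width_table()].
#' @return numeric vector of widths (meters).
#' @export
assign_width <- function(roads, is_urban, table = default_width_table()) {
  a <- roads$attrs
  is_urban <- rep_len(as.logical(is_urban), nrow(a))
  vapply(seq_len(nrow(a)), function(i) {
    hit <- table$is_highway == a$is_highway[i] &
      table$is_urban == is_urban[i] &
      table$speed_min <= a$speed_limit[i] &
      a$speed_limit[i] < table$speed_max
    if (!any(hit))
      stop("width table does not cover combination (is_highway=",
           a$is_highway[i], ", speed_limit=", a$speed_limit[i],
           ", is_urban=", is_urban[i], ")", call. = FALSE)
    table$width_m[which(hit)[1L]]
  }, numeric(1))
}

#' Keep only major ports
#'
#' Retains port features whose annual accommodated-vessel count strictly
#' exceeds the threshold ("more than" semantics).
#'
#' @param ports a port [point_layer()] carrying `vessels_per_year`.
#' @param threshold vessels per year; default 10000.
#' @return the filtered `geocov_points` layer.
#' @export
filter_major_ports <- function(ports, threshold = 10000) {
  stopifnot(inherits(ports, "geocov_points"))
  if (is.null(ports$vessels_per_year))
    stop("schema error: missing attribute 'vessels_per_year'", call. = FALSE)
  keep <- ports$vessels_per_year > threshold
  out <- ports[keep, , drop = FALSE]
  structure(out, kind = attr(ports, "kind"),
            class = c("geocov_points", "data.frame"))
}

round_key <- function(x, y) paste(round(x, 6), round(y, 6))

#' Derive the northern border line from an administrative tessellation
#'
#' Dissolves all polygons (interior edges shared by two features cancel),
#' takes the exterior boundary ring enclosing the largest area (warning if
#' the layer has several disjoint parts), and keeps the boundary segments
#' whose midpoints lie strictly within the top `northern_fraction` of the
#' boundary's y-extent. Requires a tessellation with topologically matching
#' edges (vertices coincident to 1e-6 m), as produced by census-style layers.
#'
#' @param admin a [polygon_layer()] of administrative units.
#' @param northern_fraction fraction of the y-extent, in (0, 1], defining
#'   "northern end".
#' @return a named list of 2-point segment matrices (consumable by
#'   [nearest_distance()]), with attribute `boundary` holding the full
#'   exterior ring.
#' @export
derive_border_line <- function(admin, northern_fraction = 0.1) {
  stopifnot(inherits(admin, "geocov_polygons"))
  if (length(admin$geoms) == 0L) stop("empty admin layer", call. = FALSE)
  stopifnot(northern_fraction > 0, northern_fraction <= 1)
  # collect all ring edges; interior edges appear twice and cancel
  seg_a <- character(0); seg_b <- character(0)
  coords <- new.env(parent = emptyenv())
  for (poly in admin$geoms) for (ring in poly) {
    rc <- rbind(ring, ring[1L, , drop = FALSE])
    for (i in seq_len(nrow(rc) - 1L)) {
      k1 <- round_key(rc[i, 1L], rc[i, 2L])
      k2 <- round_key(rc[i + 1L, 1L], rc[i + 1L, 2L])
      assign(k1, rc[i, ], envir = coords)
      assign(k2, rc[i + 1L, ], envir = coords)
      seg_a <- c(seg_a, k1)
      seg_b <- c(seg_b, k2)
    }
  }
  ekey <- ifelse(seg_a < seg_b, paste(seg_a, "|", seg_b),
                 paste(seg_b, "|", seg_a))
  cnt <- table(ekey)
  keep <- cnt[ekey] == 1L
  if (!any(keep)) stop("degenerate tessellation: no boundary edges",
                       call. = FALSE)
  ba <- seg_a[keep]
  bb <- seg_b[keep]
  # walk boundary edges into closed rings
  nb <- length(ba)
  used <- logical(nb)
  rings <- list()
  adj <- split(seq_len(nb), ba)
  adj2 <- split(seq_len(nb), bb)
  while (any(!used)) {
    start <- which(!used)[1L]
    used[start] <- TRUE
    path <- c(ba[start], bb[start])
    repeat {
      cur <- path[length(path)]
      nxt <- c(adj[[cur]], adj2[[cur]])
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      e <- nxt[1L]
      used[e] <- TRUE
      path <- c(path, if (ba[e] == cur) bb[e] else ba[e])
      if (path[length(path)] == path[1L]) break
    }
    rings[[length(rings) + 1L]] <- path
  }
  ring_mats <- lapply(rings, function(p) {
    m <- t(vapply(p, function(k) get(k, envir = coords), numeric(2)))
    dimnames(m) <- NULL
    if (all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
  areas <- vapply(ring_mats, function(m) abs(ring_area_signed(m)), numeric(1))
  if (length(ring_mats) > 1L)
    warning("dissolved boundary has ", length(ring_mats),
            " ring(s); using the largest-area ring", call. = FALSE)
  outer <- ring_mats[[which.max(areas)]]
  ymin <- min(outer[, 2L])
  ymax <- max(outer[, 2L])
  cutoff <- ymax - northern_fraction * (ymax - ymin)
  rc <- rbind(outer, outer[1L, , drop = FALSE])
  segs <- list()
  for (i in seq_len(nrow(rc) - 1L)) {
    midy <- (rc[i, 2L] + rc[i + 1L, 2L]) / 2
    if (midy > cutoff)
      segs[[length(segs) + 1L]] <- rc[i:(i + 1L), , drop = FALSE]
  }
  if (length(segs) == 0L)
    warning("no boundary segments in the northern fraction", call. = FALSE)
  names(segs) <- if (length(segs)) paste0("b", seq_along(segs)) else NULL
  attr(segs, "boundary") <- outer
  segs
}

#' Road-network class totals and shares
#'
#' `road_network_totals()` sums segment lengths (km) of a network by major-road
#' class; `road_class_share()` expresses the MR1 and MR2 totals as percentages
#' of the all-roads total.
#'
#' @param roads a [road_layer()].
#' @param scheme a [road_class_scheme()].
#' @return `road_network_totals()`: named numeric vector (km) with elements
#'   `ALL`, `MR1`, `MR2`; `road_class_share()`: named numeric vector (percent)
#'   with elements `MR1`, `MR2`.
#' @examples
#' road_class_share(c(ALL = 90816, MR1 = 8128, MR2 = 12194))
#' @export
road_network_totals <- function(roads, scheme = road_class_scheme()) {
  lens <- vapply(roads$geoms, polyline_length, numeric(1)) / 1000
  mem <- road_class_membership(roads, scheme)
  c(ALL = sum(lens), MR1 = sum(lens[mem[, "MR1"]]),
    MR2 = sum(lens[mem[, "MR2"]]))
}

#' @rdname road_network_totals
#' @param totals named numeric vector with elements `ALL`, `MR1`, `MR2`
#'   (any length unit, e.g. km).
#' @export
road_class_share <- function(totals) {
  stopifnot(all(c("ALL", "MR1", "MR2") %in% names(totals)))
  if (totals[["ALL"]] <= 0) stop("ALL total must be positive", call. = FALSE)
  c(MR1 = 100 * totals[["MR1"]] / totals[["ALL"]],
    MR2 = 100 * totals[["MR2"]] / totals[["ALL"]])
}
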