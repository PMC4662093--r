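# Circular-buffer summaries: clipped road-length sums under three
# weightings, areally weighted polygon counts, land-use proportions and
# gridded-emission totals.
#
# Buffer discs are approximated by an inscribed regular polygon
# (default 256 vertices, area deficit ~1e-4) for polygon overlay; polylines
# are clipped against the exact circle, which is both cheaper and exact.

DEFAULT_BUFFER_VERTICES <- 256L

#' Buffer radii presets
#'
#' Standard radii sets by variable category: traffic buffers
#' (25–1000 m), non-traffic buffers for demographic and land-use variables,
#' and the large emission buffers (3/15/30 km). Two non-traffic presets are
#' shipped because published radii sets differ on whether 50 m is included;
#' `"table_footnote"` (with 50 m) is the default, `"body_text"` omits it.
#'
#' @param category `"traffic"`, `"nontraffic"` or `"emission"`.
#' @param nontraffic_preset `"table_footnote"` or `"body_text"`.
#' @return numeric vector of radii in meters, strictly increasing.
#' @export
buffer_radii <- function(category = c("traffic", "nontraffic", "emission"),
                         nontraffic_preset = c("table_footnote", "body_text")) {
  category <- match.arg(category)
  nontraffic_preset <- match.arg(nontraffic_preset)
  switch(category,
         traffic = c(25, 50, 100, 300, 500, 1000),
         nontraffic = if (nontraffic_preset == "table_footnote")
           c(50, 100, 300, 500, 1000, 5000) else c(100, 300, 500, 1000, 5000),
         emission = c(3000, 15000, 30000))
}

buffer_summary_row <- function(site_id, radius, variable, value) {
  data.frame(site_id = site_id, radius = radius, variable = variable,
             value = value, stringsAsFactors = FALSE)
}

#' Sum of road lengths within a buffer
#'
#' Selects segments of the requested major-road class, clips them at the
#' buffer boundary (so sums are continuous in the radius), and totals the
#' clipped lengths, optionally weighted by lane count and per-lane width.
#' An empty intersection is a valid value of 0, not a missing value.
#'
#' Units follow reporting convention: `"length"` and `"length_x_lanes"` in
#' km (lane-km), `"length_x_lanes_x_width"` in 1000 m².
#'
#' @param site one-row [monitoring_sites()] table (or any row subset; all
#'   rows are computed).
#' @param radius buffer radius in meters, > 0.
#' @param roads a [road_layer()].
#' @param road_class `"ALL"`, `"MR1"` or `"MR2"`.
#' @param weighting `"length"`, `"length_x_lanes"` or
#'   `"length_x_lanes_x_width"`.
#' @param width_table a [width_table()]; needed for the width weighting.
#' @param urbanized urbanized-area [polygon_layer()] used to pick urban vs
#'   non-urban widths; `NULL` treats all segments as non-urban.
#' @param scheme a [road_class_scheme()].
#' @param is_urban optional precomputed logical vector (overrides
#'   `urbanized`), useful when summing many buffers over one network.
#' @return a data frame of buffer summaries
#'   (`site_id`, `radius`, `variable`, `value`).
#' @export
buffer_road_sum <- function(site, radius, roads, road_class = "ALL",
                            weighting = c("length", "length_x_lanes",
                                          "length_x_lanes_x_width"),
                            width_table = default_width_table(),
                            urbanized = NULL,
                            scheme = road_class_scheme(),
                            is_urban = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(radius > 0)
  mem <- road_class_membership(roads, scheme)
  sel <- which(mem[, road_class])
  w <- rep(1, nrow(roads$attrs))
  if (weighting != "length") {
    w <- as.numeric(roads$attrs$lanes)
    if (weighting == "length_x_lanes_x_width") {
      if (is.null(is_urban)) {
        is_urban <- if (is.null(urbanized)) rep(FALSE, nrow(roads$attrs))
                    else classify_urban(roads, urbanized)
      }
      w <- w * assign_width(roads, is_urban, width_table)
    }
  }
  # meters -> km for lengths, m^2 -> 1000 m^2 for the width weighting
  unit <- 1000
  vname <- paste0("roadsum.", road_class, ".", weighting)
  out <- lapply(seq_len(nrow(site)), function(i) {
    v <- 0
    for (k in sel) {
      len <- polyline_length_in_circle(roads$geoms[[k]],
                                       site$x[i], site$y[i], radius)
      v <- v + len * w[k]
    }
    buffer_summary_row(site$site_id[i], radius, vname, v / unit)
  })
  do.call(rbind, out)
}

# shared worker: sum over polygons of value_j * area(poly_j /\ buffer)/area_j
areal_weight_worker <- function(cx, cy, radius, layer, values, n_vertices) {
  clip <- regular_ngon(cx, cy, radius, n_vertices)
  total <- 0
  for (j in seq_along(layer$geoms)) {
    vj <- values[j]
    if (is.na(vj) || vj == 0) next
    if (!bbox_overlaps_disc(polygon_bbox(layer$geoms[[j]]), cx, cy, radius))
      next
    aij <- clip_polygon_convex_area(layer$geoms[[j]], clip)
    if (aij <= 0) next  # zero-area touch contributes nothing
    total <- total + vj * aij / layer$areas[j]
  }
  total
}

#' Areally weighted attribute sum within a buffer
#'
#' Apportions each polygon's count attribute to the buffer in proportion to
#' the intersected area fraction and sums the contributions:
#' \deqn{P_i = \sum_j P_j \, A_{ij} / A_j}
#' where \eqn{A_{ij}} is the area of polygon \eqn{j} intersected with buffer
#' \eqn{i} and \eqn{A_j} the polygon's area. Assumes uniform within-polygon
#' density. A polygon merely touching the buffer (zero intersection area)
#' contributes nothing.
#'
#' @inheritParams buffer_road_sum
#' @param zones a [polygon_layer()] carrying the attribute.
#' @param attribute name of the numeric attribute to aggregate.
#' @param n_vertices vertex count of the buffer-disc polygon approximation.
#' @return a data frame of buffer summaries.
#' @export
areal_weighted_sum <- function(site, radius, zones, attribute,
                               n_vertices = DEFAULT_BUFFER_VERTICES) {
  stopifnot(inherits(zones, "geocov_polygons"), radius > 0)
  if (!attribute %in% names(zones$attrs))
    stop("attribute '", attribute, "' not found on layer", call. = FALSE)
  values <- as.numeric(zones$attrs[[attribute]])
  out <- lapply(seq_len(nrow(site)), function(i) {
    buffer_summary_row(site$site_id[i], radius, paste0("awsum.", attribute),
                       areal_weight_worker(site$x[i], site$y[i], radius,
                                           zones, values, n_vertices))
  })
  do.call(rbind, out)
}

#' Land-use class proportion within a buffer
#'
#' Area of the given land-cover class intersected with the buffer, divided
#' by the buffer area. Uses the buffer polygon's own area as denominator so
#' that proportions over a tessellating mosaic sum to exactly 1. Classes
#' absent from the buffer yield 0.
#'
#' @inheritParams areal_weighted_sum
#' @param landcover a land-cover [polygon_layer()] with a `class_code`
#'   attribute.
#' @param class_code land-use class to measure.
#' @return a data frame of buffer summaries with values in [0, 1].
#' @export
land_use_proportion <- function(site, radius, landcover, class_code,
                                n_vertices = DEFAULT_BUFFER_VERTICES) {
  stopifnot(inherits(landcover, "geocov_polygons"), radius > 0)
  if (!"class_code" %in% names(landcover$attrs))
    stop("landcover layer needs a class_code attribute", call. = FALSE)
  sel <- which(landcover$attrs$class_code == class_code)
  out <- lapply(seq_len(nrow(site)), function(i) {
    clip <- regular_ngon(site$x[i], site$y[i], radius, n_vertices)
    denom <- ring_area_signed(clip)
    num <- 0
    for (j in sel) {
      if (!bbox_overlaps_disc(polygon_bbox(landcover$geoms[[j]]),
                              site$x[i], site$y[i], radius)) next
      num <- num + max(0, clip_polygon_convex_area(landcover$geoms[[j]], clip))
    }
    buffer_summary_row(site$site_id[i], radius, paste0("landuse.", class_code),
                       min(1, num / denom))
  })
  do.call(rbind, out)
}

#' Convert an emission grid table to cell polygons
#'
#' Each distinct bottom-left corner becomes the square cell
#' `[x, x + cell_size) x [y, y + cell_size)`; per-pollutant attributes are the
#' point + line + area source estimates summed within the cell, so adjacent
#' cells tile the grid with zero overlap.
#'
#' @param table an [emission_grid_table()].
#' @return a [polygon_layer()] of kind `"emission_cell"` with one numeric
#'   attribute per pollutant present in the table.
#' @export
emission_cells_to_polygons <- function(table) {
  stopifnot(inherits(table, "geocov_emissions"))
  cs <- attr(table, "cell_size")
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  cells <- unique(df[, c("corner_x", "corner_y")])
  cells <- cells[order(cells$corner_x, cells$corner_y), , drop = FALSE]
  polls <- sort(unique(df$pollutant))
  attrs <- data.frame(feature_id = paste0("c", seq_len(nrow(cells))),
                      stringsAsFactors = FALSE)
  ck <- paste(df$corner_x, df$corner_y)
  cellk <- paste(cells$corner_x, cells$corner_y)
  for (p in polls) {
    sums <- tapply(df$estimate[df$pollutant == p], ck[df$pollutant == p], sum)
    v <- as.numeric(sums[cellk])
    v[is.na(v)] <- 0
    attrs[[p]] <- v
  }
  geoms <- lapply(seq_len(nrow(cells)), function(i) {
    x <- cells$corner_x[i]
    y <- cells$corner_y[i]
    list(rbind(c(x, y), c(x + cs, y), c(x + cs, y + cs), c(x, y + cs)))
  })
  polygon_layer(geoms, attrs = attrs, layer_kind = "emission_cell")
}

#' Emission total within a buffer
#'
#' Areally weighted sum ([areal_weighted_sum()]) of a pollutant attribute
#' over emission cell polygons; conventionally run at 3, 15 and 30 km radii.
#'
#' @inheritParams areal_weighted_sum
#' @param emission_polygons layer from [emission_cells_to_polygons()].
#' @param pollutant pollutant attribute name (e.g. `"PM10"`).
#' @return a data frame of buffer summaries.
#' @export
emission_buffer_sum <- function(site, radius, emission_polygons, pollutant,
                                n_vertices = DEFAULT_BUFFER_VERTICES) {
  if (!pollutant %in% names(emission_polygons$attrs))
    stop("unknown pollutant '", pollutant, "'", call. = FALSE)
  out <- areal_weighted_sum(site, radius, emission_polygons, pollutant,
                            n_vertices = n_vertices)
  out$variable <- paste0("emission.", pollutant)
  out
}
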