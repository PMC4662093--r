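# Domain types: validated in-memory representations of every vector, raster
# and tabular input the covariate pipeline consumes. All coordinates must be
# in one shared projected CRS in meters; loaders enforce this boundary.

ROAD_TYPES <- c("national_highway", "metro_city_highway", "general_national_road",
                "metro_city_road", "gov_provincial_road", "provincial_road",
                "district_road", "highway_link_ramp")

SITE_TYPES <- c("urban_background", "urban_roadside", "other")

LAYER_KINDS <- c("census", "landcover", "admin_district", "emission_cell",
                 "urbanized_area")

POINT_KINDS <- c("rail_station", "subway_station", "bus_stop", "airport", "port")

POLLUTANTS <- c("CO", "NOx", "SOx", "TSP", "PM10", "VOC", "NH3")

EMISSION_SOURCES <- c("point", "line", "area")

#' Monitoring-site set
#'
#' A validated table of point locations at which covariates are computed,
#' e.g. regulatory air-quality monitors. Coordinates are projected meters.
#'
#' @param site_id character vector of unique identifiers.
#' @param x,y numeric projected coordinates (meters).
#' @param site_type site classification, one of `"urban_background"`,
#'   `"urban_roadside"`, `"other"`.
#' @return a `geocov_sites` data frame with columns
#'   `site_id`, `x`, `y`, `site_type`.
#' @examples
#' monitoring_sites(c("a", "b"), c(0, 100), c(0, 50))
#' @export
monitoring_sites <- function(site_id, x, y, site_type = "other") {
  site_id <- as.character(site_id)
  x <- as.numeric(x)
  y <- as.numeric(y)
  site_type <- rep_len(as.character(site_type), length(site_id))
  if (anyDuplicated(site_id))
    stop("duplicate site_id: ",
         paste(unique(site_id[duplicated(site_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("site coordinates must be finite", call. = FALSE)
  bad <- !site_type %in% SITE_TYPES
  if (any(bad))
    stop("unknown site_type: ", paste(unique(site_type[bad]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(site_id = site_id, x = x, y = y, site_type = site_type,
                    stringsAsFactors = FALSE)
  class(out) <- c("geocov_sites", "data.frame")
  out
}

#' Road-network layer
#'
#' Polyline road segments with the attributes used for road classification
#' (major-road membership), width assignment and lane weighting.
#'
#' @param geoms list of coordinate matrices (one polyline per segment,
#'   at least 2 vertices each).
#' @param road_type character vector; one of the eight network classes
#'   (`national_highway`, `metro_city_highway`, `general_national_road`,
#'   `metro_city_road`, `gov_provincial_road`, `provincial_road`,
#'   `district_road`, `highway_link_ramp`).
#' @param lanes positive integer lane counts (as given in the source data;
#'   whether counts are per direction or total is a property of the source).
#' @param speed_limit speed limits in km/h, > 0.
#' @param is_highway logical highway flag used by the width table.
#' @param feature_id optional ids; defaults to `"r1"`, `"r2"`, ...
#' @return a `geocov_roads` object: list with `geoms` and `attrs`.
#' @export
road_layer <- function(geoms, road_type, lanes, speed_limit, is_highway,
                       feature_id = NULL) {
  n <- length(geoms)
  if (is.null(feature_id)) feature_id <- paste0("r", seq_len(n))
  geoms <- lapply(geoms, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  nv <- vapply(geoms, nrow, integer(1))
  if (any(nv < 2L))
    stop("road geometry with fewer than 2 vertices: feature ",
         paste(feature_id[nv < 2L], collapse = ", "), call. = FALSE)
  road_type <- rep_len(as.character(road_type), n)
  bad <- !road_type %in% ROAD_TYPES
  if (any(bad))
    stop("unknown road_type: ", paste(unique(road_type[bad]), collapse = ", "),
         call. = FALSE)
  lanes <- rep_len(as.integer(lanes), n)
  speed_limit <- rep_len(as.numeric(speed_limit), n)
  is_highway <- rep_len(as.logical(is_highway), n)
  if (any(lanes < 1L)) stop("lanes must be >= 1", call. = FALSE)
  if (any(speed_limit <= 0)) stop("speed_limit must be > 0", call. = FALSE)
  attrs <- data.frame(feature_id = as.character(feature_id),
                      road_type = road_type, lanes = lanes,
                      speed_limit = speed_limit, is_highway = is_highway,
                      stringsAsFactors = FALSE)
  structure(list(geoms = geoms, attrs = attrs), class = "geocov_roads")
}

#' Zonal polygon layer
#'
#' Polygons carrying named numeric attributes: census output areas, land-cover
#' patches, administrative districts, emission grid cells or urbanized areas.
#' Zero-area features are rejected at construction; census attribute values
#' must be nonnegative.
#'
#' @param geoms list of polygons; each polygon is a list of ring coordinate
#'   matrices (exterior first, holes after) or a single ring matrix.
#' @param attrs data frame of per-feature attributes (may be 0-column);
#'   a `feature_id` column is added when absent.
#' @param layer_kind one of `"census"`, `"landcover"`, `"admin_district"`,
#'   `"emission_cell"`, `"urbanized_area"`.
#' @return a `geocov_polygons` object: list with `geoms`, `attrs`,
#'   `layer_kind`; per-feature areas cached in `areas`.
#' @export
polygon_layer <- function(geoms, attrs = NULL, layer_kind = "census") {
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  geoms <- lapply(geoms, function(g) {
    if (is.matrix(g) || is.data.frame(g)) g <- list(as.matrix(g))
    normalize_polygon(g)
  })
  n <- length(geoms)
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_len(n))
  attrs <- as.data.frame(attrs, stringsAsFactors = FALSE)
  if (nrow(attrs) != n) stop("attrs rows must match geometry count", call. = FALSE)
  if (is.null(attrs$feature_id)) attrs$feature_id <- paste0("f", seq_len(n))
  attrs$feature_id <- as.character(attrs$feature_id)
  areas <- vapply(geoms, polygon_area, numeric(1))
  if (any(areas <= 0))
    stop("zero-area polygon feature(s): ",
         paste(attrs$feature_id[areas <= 0], collapse = ", "), call. = FALSE)
  if (layer_kind == "census") {
    num <- vapply(attrs, is.numeric, logical(1))
    for (nm in names(attrs)[num]) {
      v <- attrs[[nm]]
      if (any(v < 0, na.rm = TRUE))
        stop("negative census attribute '", nm, "'", call. = FALSE)
    }
  }
  structure(list(geoms = geoms, attrs = attrs, layer_kind = layer_kind,
                 areas = areas),
            class = "geocov_polygons")
}

#' Point-feature layer
#'
#' Transportation depots and similar point features. Port layers must carry a
#' nonnegative `vessels_per_year` attribute.
#'
#' @param df data frame with numeric `x`, `y` columns plus attributes.
#' @param kind one of `"rail_station"`, `"subway_station"`, `"bus_stop"`,
#'   `"airport"`, `"port"`.
#' @return a `geocov_points` data frame with attribute `kind`.
#' @export
point_layer <- function(df, kind) {
  kind <- match.arg(kind, POINT_KINDS)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("point layer needs x and y columns", call. = FALSE)
  if (is.null(df$feature_id)) df$feature_id <- paste0("p", seq_len(nrow(df)))
  df$feature_id <- as.character(df$feature_id)
  if (kind == "port") {
    if (is.null(df$vessels_per_year))
      stop("schema error: port layer missing attribute 'vessels_per_year'",
           call. = FALSE)
    if (any(df$vessels_per_year < 0, na.rm = TRUE))
      stop("vessels_per_year must be >= 0", call. = FALSE)
  }
  structure(df, kind = kind, class = c("geocov_points", "data.frame"))
}

#' Regular raster grid
#'
#' A regular grid of cell values with its origin at the *bottom-left corner*
#' of cell (row 1, col 1); row index increases with y. Cell footprints follow
#' the half-open convention `[x0 + c*(i-1), x0 + c*i)`.
#'
#' @param origin_x,origin_y coordinates (meters) of the grid's lower-left corner.
#' @param cell_size cell edge length in meters, > 0.
#' @param values numeric matrix of cell values; `values[1, 1]` is the
#'   bottom-left cell.
#' @param nodata sentinel replaced by `NA` on read (`NA` to disable).
#' @return a `geocov_raster` object.
#' @export
raster_grid <- function(origin_x, origin_y, cell_size, values, nodata = NA) {
  stopifnot(cell_size > 0, is.matrix(values))
  values <- `storage.mode<-`(values, "double")
  if (!is.na(nodata)) values[values == nodata] <- NA_real_
  structure(list(origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 n_rows = nrow(values), n_cols = ncol(values),
                 values = values, nodata = nodata),
            class = "geocov_raster")
}

same_grid_geometry <- function(a, b, tol = 1e-6) {
  abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' NDVI composite stack
#'
#' An ordered set of byte-scaled (0-255) vegetation-index composite rasters
#' sharing one grid geometry; typically 36 ten-day composites per year.
#'
#' @param dates `Date` vector (one per composite).
#' @param rasters list of [raster_grid()] objects on identical geometry.
#' @param value_range permitted value range; values outside it (other than
#'   `NA`) are rejected.
#' @return a `geocov_ndvi_stack` object, composites sorted by date.
#' @export
ndvi_stack <- function(dates, rasters, value_range = c(0, 255)) {
  dates <- as.Date(dates)
  if (length(dates) != length(rasters))
    stop("dates and rasters lengths differ", call. = FALSE)
  if (length(rasters) == 0L) stop("empty NDVI stack", call. = FALSE)
  g0 <- rasters[[1L]]
  for (r in rasters) {
    if (!same_grid_geometry(r, g0))
      stop("NDVI composites must share grid geometry", call. = FALSE)
    v <- r$values
    if (any(v < value_range[1L] | v > value_range[2L], na.rm = TRUE))
      stop("NDVI values outside declared range [",
           value_range[1L], ", ", value_range[2L], "]", call. = FALSE)
  }
  ord <- order(dates)
  structure(list(dates = dates[ord], rasters = rasters[ord],
                 value_range = value_range),
            class = "geocov_ndvi_stack")
}

#' Gridded emission-inventory table
#'
#' Annual emission estimates on a regular grid, keyed by the *bottom-left
#' corner* of each cell, split by source type (point/line/area) and pollutant.
#'
#' @param df data frame with columns `corner_x`, `corner_y`, `source`
#'   (`point`/`line`/`area`), `pollutant` (one of CO, NOx, SOx, TSP, PM10,
#'   VOC, NH3) and `estimate` (mass/year, >= 0).
#' @param cell_size grid cell edge in meters (default 1000).
#' @return a `geocov_emissions` data frame with attribute `cell_size`.
#' @export
emission_grid_table <- function(df, cell_size = 1000) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("corner_x", "corner_y", "source", "pollutant", "estimate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: emission table missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!df$source %in% EMISSION_SOURCES))
    stop("unknown emission source type", call. = FALSE)
  if (any(!df$pollutant %in% POLLUTANTS))
    stop("unknown pollutant; expected one of ",
         paste(POLLUTANTS, collapse = ", "), call. = FALSE)
  if (any(df$estimate < 0)) stop("emission estimates must be >= 0", call. = FALSE)
  key <- paste(df$corner_x, df$corner_y, df$source, df$pollutant)
  if (anyDuplicated(key))
    stop("duplicate (cell, source, pollutant) rows in emission table",
         call. = FALSE)
  structure(df, cell_size = cell_size,
            class = c("geocov_emissions", "data.frame"))
}

#' Major-road classification scheme
#'
#' MR1 is defined by road type (by default national and metropolitan-city
#' highways); MR2 is MR1 plus any road with strictly more than
#' `mr2_lane_threshold` lanes.
#'
#' @param mr1_types road types defining the primary major-road class.
#' @param mr2_lane_threshold lane count above which (strictly) other roads
#'   join the secondary class; default 6.
#' @return a `road_class_scheme` object.
#' @export
road_class_scheme <- function(mr1_types = c("national_highway",
                                            "metro_city_highway"),
                              mr2_lane_threshold = 6L) {
  mr1_types <- as.character(mr1_types)
  if (length(mr1_types) == 0L) stop("mr1_types must be non-empty", call. = FALSE)
  bad <- !mr1_types %in% ROAD_TYPES
  if (any(bad)) stop("unknown road types in mr1_types: ",
                     paste(mr1_types[bad], collapse = ", "), call. = FALSE)
  if (mr2_lane_threshold < 1L)
    stop("mr2_lane_threshold must be >= 1", call. = FALSE)
  structure(list(mr1_types = mr1_types,
                 mr2_lane_threshold = as.integer(mr2_lane_threshold)),
            class = "road_class_scheme")
}

#' Road-width lookup table
#'
#' Maps (highway flag, speed band, urban flag) to a per-lane road width in
#' meters. Speed bands are half-open `[speed_min, speed_max)`. The shipped
#' default ([default_width_table()]) uses plausible lane-width bands and is
#' not an authoritative reproduction of any national rule.
#'
#' @param df data frame with columns `is_highway` (logical), `speed_min`,
#'   `speed_max` (km/h), `is_urban` (logical), `width_m` (> 0).
#' @return a `width_table` data frame.
#' @export
width_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("is_highway", "speed_min", "speed_max", "is_urban", "width_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: width table missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$width_m <= 0)) stop("widths must be > 0", call. = FALSE)
  if (any(df$speed_max <= df$speed_min))
    stop("speed bands must have speed_max > speed_min", call. = FALSE)
  structure(df, class = c("width_table", "data.frame"))
}

#' Default per-lane road-width table
#'
#' Plausible per-lane widths by highway status, speed band and urban status;
#' a stand-in for jurisdiction-specific road-design rules, clearly
#' non-authoritative. Users with real width regulations should supply their
#' own table via [width_table()] / [read_width_table()].
#'
#' @return a `width_table` covering all speed limits in (0, 200) km/h.
#' @export
default_width_table <- function() {
  grid <- expand.grid(is_highway = c(FALSE, TRUE),
                      band = c("low", "mid", "high"),
                      is_urban = c(FALSE, TRUE),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$speed_min <- c(low = 0, mid = 60, high = 80)[grid$band]
  grid$speed_max <- c(low = 60, mid = 80, high = 200)[grid$band]
  grid$width_m <- ifelse(grid$is_highway, 3.6,
                         ifelse(grid$band == "high", 3.5,
                                ifelse(grid$band == "mid", 3.25, 3.0)))
  grid$width_m <- ifelse(!grid$is_highway & grid$is_urban,
                         pmin(grid$width_m, 3.0), grid$width_m)
  width_table(grid[, c("is_highway", "speed_min", "speed_max",
                       "is_urban", "width_m")])
}

#' Join a keyed attribute table onto a polygon layer
#'
#' One-to-one join of tabular data (e.g. census counts keyed by output-area
#' id) onto polygon features. Unmatched polygons keep their geometry and get
#' `NA` for the joined columns (with a warning); duplicate keys in the table
#' and empty joins are errors.
#'
#' @param layer a [polygon_layer()].
#' @param table data frame of attribute rows.
#' @param key name of the id column present in both `layer$attrs` and `table`.
#' @return the enriched `geocov_polygons` layer.
#' @export
join_table_to_layer <- function(layer, table, key) {
  stopifnot(inherits(layer, "geocov_polygons"))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!key %in% names(layer$attrs))
    stop("key '", key, "' not found in layer attributes", call. = FALSE)
  if (!key %in% names(table))
    stop("key '", key, "' not found in table", call. = FALSE)
  if (anyDuplicated(table[[key]]))
    stop("duplicate key values in table: ",
         paste(unique(table[[key]][duplicated(table[[key]])]), collapse = ", "),
         call. = FALSE)
  idx <- match(layer$attrs[[key]], table[[key]])
  if (all(is.na(idx)))
    stop("no rows matched on key '", key, "' (wrong key?)", call. = FALSE)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " polygon(s) unmatched on key '", key,
            "'; attributes set to NA", call. = FALSE)
  add <- setdiff(names(table), key)
  for (nm in add) layer$attrs[[nm]] <- table[[nm]][idx]
  layer
}
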