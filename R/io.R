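# Plain-text I/O layer.
#
# Vector layers travel as CSV with a `wkt` geometry column; rasters as ESRI
# ASCII grid (.asc); everything else as plain CSV. An optional leading
# comment line "# crs: <name>" declares the CRS of a vector file; when
# present it must name a projected, meter-based system — geographic
# (degree-based) systems are rejected with an instruction to reproject.
# This keeps the whole pipeline text-only and CRS-agnostic: all inputs must
# simply share one projected CRS.

GEOGRAPHIC_CRS_PATTERN <- "(?i)(4326|4019|4269|longlat|wgs ?84$|epsg:43|degree)"

#' Check that a CRS description names a projected meter-based system
#'
#' @param crs a CRS description string or `NULL`/`NA` (accepted: unknown CRS
#'   is treated as "trusted to be projected").
#' @return invisibly, the crs.
#' @export
assert_projected_crs <- function(crs) {
  if (is.null(crs) || length(crs) == 0L || is.na(crs) || !nzchar(crs))
    return(invisible(crs))
  if (grepl(GEOGRAPHIC_CRS_PATTERN, crs, perl = TRUE))
    stop("layer declares a geographic (degree-based) CRS '", crs,
         "'; reproject to a projected meter-based CRS before loading",
         call. = FALSE)
  invisible(crs)
}

read_csv_with_crs <- function(path) {
  first <- readLines(path, n = 1L)
  crs <- NA_character_
  skip <- 0L
  if (grepl("^#\\s*crs\\s*:", first)) {
    crs <- trimws(sub("^#\\s*crs\\s*:", "", first))
    skip <- 1L
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, skip = skip,
                        fileEncoding = "UTF-8")
  attr(df, "crs") <- crs
  df
}

write_csv_with_crs <- function(df, path, crs = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(crs) && !is.na(crs) && nzchar(crs))
    writeLines(paste0("# crs: ", crs), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error: ", what, " missing required attribute(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

apply_schema <- function(df, schema) {
  if (is.null(schema)) return(df)
  # schema maps canonical name -> file column name
  for (canon in names(schema)) {
    src <- schema[[canon]]
    if (!src %in% names(df))
      stop("schema error: declared column '", src, "' for '", canon,
           "' not present in file", call. = FALSE)
    names(df)[names(df) == src] <- canon
  }
  df
}

#' Load a vector layer from a WKT-geometry CSV file
#'
#' Reads a CSV file with a `wkt` geometry column plus attribute columns and
#' validates it into the matching in-memory type. Geometry type must match
#' `layer_kind`: polygons for zonal kinds, linestrings for `"road"`, points
#' for depot kinds. An optional `# crs: <name>` first line is validated with
#' [assert_projected_crs()].
#'
#' @param path CSV file path.
#' @param layer_kind one of the zonal kinds (`census`, `landcover`,
#'   `admin_district`, `emission_cell`, `urbanized_area`), `"road"`, or a
#'   point kind (`rail_station`, `subway_station`, `bus_stop`, `airport`,
#'   `port`).
#' @param schema optional named list mapping canonical attribute names to
#'   the column names used in the file.
#' @return a [polygon_layer()], [road_layer()] or [point_layer()].
#' @export
load_vector_layer <- function(path, layer_kind, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_csv_with_crs(path)
  assert_projected_crs(attr(df, "crs"))
  df <- apply_schema(df, schema)
  require_columns(df, "wkt", basename(path))
  geoms <- lapply(df$wkt, parse_wkt)
  types <- vapply(geoms, `[[`, character(1), "type")
  df$wkt <- NULL
  if (layer_kind %in% LAYER_KINDS) {
    if (!all(types %in% c("POLYGON", "MULTIPOLYGON")))
      stop("layer_kind '", layer_kind, "' expects polygon geometry; found ",
           paste(setdiff(types, c("POLYGON", "MULTIPOLYGON")), collapse = ", "),
           call. = FALSE)
    polys <- lapply(geoms, function(g) {
      if (g$type == "POLYGON") g$coords else {
        # flatten multipolygon parts into one ring list (area-equivalent)
        do.call(c, g$coords)
      }
    })
    polygon_layer(polys, attrs = df, layer_kind = layer_kind)
  } else if (layer_kind == "road") {
    if (!all(types == "LINESTRING"))
      stop("road layer expects LINESTRING geometry", call. = FALSE)
    require_columns(df, c("road_type", "lanes", "speed_limit", "is_highway"),
                    "road layer")
    road_layer(lapply(geoms, `[[`, "coords"),
               road_type = df$road_type, lanes = df$lanes,
               speed_limit = df$speed_limit,
               is_highway = as.logical(df$is_highway),
               feature_id = df$feature_id)
  } else if (layer_kind %in% POINT_KINDS) {
    if (!all(types == "POINT"))
      stop("point layer expects POINT geometry", call. = FALSE)
    xy <- t(vapply(geoms, `[[`, numeric(2), "coords"))
    df$x <- xy[, 1L]
    df$y <- xy[, 2L]
    point_layer(df, kind = layer_kind)
  } else {
    stop("unknown layer_kind: ", layer_kind, call. = FALSE)
  }
}

#' Write a vector layer to a WKT-geometry CSV file
#'
#' Inverse of [load_vector_layer()]; round-trips feature count, attributes
#' and coordinates.
#'
#' @param layer a `geocov_polygons`, `geocov_roads` or `geocov_points` object.
#' @param path output CSV path.
#' @param crs optional CRS name written as a `# crs:` header line.
#' @return invisibly, `path`.
#' @export
write_vector_layer <- function(layer, path, crs = NULL) {
  if (inherits(layer, "geocov_polygons")) {
    df <- layer$attrs
    df$wkt <- vapply(layer$geoms, function(p) write_wkt("POLYGON", p),
                     character(1))
  } else if (inherits(layer, "geocov_roads")) {
    df <- layer$attrs
    df$wkt <- vapply(layer$geoms, function(l) write_wkt("LINESTRING", l),
                     character(1))
  } else if (inherits(layer, "geocov_points")) {
    df <- as.data.frame(layer, stringsAsFactors = FALSE)
    df$wkt <- vapply(seq_len(nrow(df)), function(i) {
      write_wkt("POINT", c(df$x[i], df$y[i]))
    }, character(1))
    df$x <- NULL
    df$y <- NULL
  } else {
    stop("unsupported layer class", call. = FALSE)
  }
  write_csv_with_crs(df, path, crs)
  invisible(path)
}

#' Read monitoring sites from CSV
#'
#' Expects columns `site_id`, `x`, `y` and optionally `site_type`.
#'
#' @param path CSV file path.
#' @return a [monitoring_sites()] table.
#' @export
read_sites_csv <- function(path) {
  df <- read_csv_with_crs(path)
  assert_projected_crs(attr(df, "crs"))
  require_columns(df, c("site_id", "x", "y"), "site list")
  monitoring_sites(df$site_id, df$x, df$y,
                   if (is.null(df$site_type)) "other" else df$site_type)
}

#' @rdname read_sites_csv
#' @param sites a `geocov_sites` table.
#' @param crs optional CRS name for the header line.
#' @export
write_sites_csv <- function(sites, path, crs = NULL) {
  write_csv_with_crs(as.data.frame(sites), path, crs)
  invisible(path)
}

#' Read / write a raster as ESRI ASCII grid
#'
#' The `.asc` header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) is followed by rows from the top of the grid down, as the
#' format prescribes; in memory row 1 is the *bottom* row.
#'
#' @param path file path.
#' @return [read_ascii_grid()]: a [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z_]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows
  nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # file top row = max y
  raster_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, m,
              nodata = if (is.null(hdr$nodata_value)) NA else hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @param raster a [raster_grid()].
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  m <- raster$values
  m[is.na(m)] <- nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste("ncols", raster$n_cols),
               paste("nrows", raster$n_rows),
               paste("xllcorner",
                     format(raster$origin_x, scientific = FALSE, trim = TRUE)),
               paste("yllcorner",
                     format(raster$origin_y, scientific = FALSE, trim = TRUE)),
               paste("cellsize",
                     format(raster$cell_size, scientific = FALSE, trim = TRUE)),
               paste("NODATA_value", nodata)), con)
  for (r in rev(seq_len(raster$n_rows)))
    writeLines(paste(format(m[r, ], scientific = FALSE, trim = TRUE,
                            digits = 15), collapse = " "), con)
  invisible(path)
}

#' Read a road-width table from CSV
#'
#' Columns: `is_highway`, `speed_min`, `speed_max`, `is_urban`, `width_m`
#' with half-open speed bands `[speed_min, speed_max)`.
#'
#' @param path CSV file path.
#' @return a [width_table()].
#' @export
read_width_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_highway <- as.logical(df$is_highway)
  df$is_urban <- as.logical(df$is_urban)
  width_table(df)
}

#' Read an emission grid table from CSV
#'
#' Columns: `corner_x`, `corner_y`, `source`, `pollutant`, `estimate`.
#'
#' @param path CSV file path.
#' @param cell_size grid cell edge in meters.
#' @return an [emission_grid_table()].
#' @export
read_emission_table <- function(path, cell_size = 1000) {
  emission_grid_table(utils::read.csv(path, stringsAsFactors = FALSE),
                      cell_size = cell_size)
}

#' Read an NDVI stack via a manifest CSV
#'
#' The manifest has columns `date` (ISO 8601) and `path` (ASCII-grid file,
#' relative paths resolved against the manifest's directory).
#'
#' @param manifest_path manifest CSV path.
#' @return an [ndvi_stack()].
#' @export
read_ndvi_stack <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  require_columns(man, c("date", "path"), "NDVI manifest")
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  ndvi_stack(as.Date(man$date), lapply(paths, read_ascii_grid))
}
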