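# Declarative variable catalog and pipeline orchestration: expands the
# eight-category taxonomy into concrete variable definitions, evaluates every
# (site, variable) cell against a bundle of loaded layers, and writes the
# resulting covariate table.

LANDUSE_CLASSES <- c(
  # medium-level urban classes
  "residential", "industrial", "commercial", "cultural", "transportation",
  "public_facility",
  # high-level non-urban classes
  "agricultural", "forest", "grassland", "wetland", "bare_ground", "water")

DEPOT_KINDS <- c("rail_station", "subway_station", "bus_stop", "airport", "port")

#' Default pipeline configuration
#'
#' Names the census count attributes, land-use classes, pollutants, radii
#' presets, major-road scheme and elevation parameters that
#' [build_default_catalog()] expands. The census breakdown (29 attributes:
#' residents by gender and age band, households, housing by type and
#' construction era, companies and employees by business category) is one
#' defensible reading of typical census output-area tables; real deployments
#' override it to match their source schema.
#'
#' @param nontraffic_preset non-traffic radii preset name, see
#'   [buffer_radii()].
#' @return a named list of configuration entries.
#' @export
default_config <- function(nontraffic_preset = "table_footnote") {
  business <- c("manufacturing", "construction", "wholesale_retail",
                "lodging_restaurant", "transport_business", "finance",
                "services")
  list(
    census_attributes = c(
      "pop_total", "pop_male", "pop_female",
      "pop_age_0_14", "pop_age_15_64", "pop_age_65plus",
      "households",
      "housing_total", "housing_detached", "housing_apartment",
      "housing_row", "housing_pre1990", "housing_post1990",
      paste0("companies_", c("total", business)),
      paste0("employees_", c("total", business))),
    landuse_classes = LANDUSE_CLASSES,
    pollutants = POLLUTANTS,
    traffic_radii = buffer_radii("traffic"),
    nontraffic_radii = buffer_radii("nontraffic", nontraffic_preset),
    emission_radii = buffer_radii("emission"),
    road_classes = c("ALL", "MR1", "MR2"),
    road_weightings = c("length", "length_x_lanes", "length_x_lanes_x_width"),
    mr1_types = c("national_highway", "metro_city_highway"),
    mr2_lane_threshold = 6L,
    major_port_threshold = 10000,
    border_northern_fraction = 0.1,
    relative_elevation_rings = c(1000, 5000),
    relative_elevation_thresholds = c(20, 50),
    relative_elevation_ring_width = 30,
    buffer_vertices = DEFAULT_BUFFER_VERTICES
  )
}

catalog_row <- function(name, category, op, ...) {
  params <- list(...)
  data.frame(name = name, category = category, op = op,
             radius = params$radius %||NA% NA_real_,
             road_class = params$road_class %||NA% NA_character_,
             weighting = params$weighting %||NA% NA_character_,
             attribute = params$attribute %||NA% NA_character_,
             class_code = params$class_code %||NA% NA_character_,
             pollutant = params$pollutant %||NA% NA_character_,
             target = params$target %||NA% NA_character_,
             ring_radius = params$ring_radius %||NA% NA_real_,
             threshold = params$threshold %||NA% NA_real_,
             direction = params$direction %||NA% NA_character_,
             stringsAsFactors = FALSE)
}

`%||NA%` <- function(a, b) if (is.null(a)) b else a

#' Expand the default variable catalog
#'
#' Expands the eight-category taxonomy into one definition per variable:
#' traffic distances and road sums (classes x radii x weightings) plus
#' registered vehicles; demographic areal-weighted counts; land-use
#' proportions; depot distances; physical-geography distances; emission
#' totals; NDVI summaries; and absolute/relative elevation. Variable names
#' follow the deterministic template `category.metric[.class][.radius]`.
#'
#' @param config a configuration list, see [default_config()].
#' @return a `geocov_catalog` data frame, one row per variable, with
#'   parameter columns (`radius`, `road_class`, `weighting`, `attribute`,
#'   `class_code`, `pollutant`, `target`, `ring_radius`, `threshold`,
#'   `direction`).
#' @export
build_default_catalog <- function(config = default_config()) {
  bad <- setdiff(config$landuse_classes, LANDUSE_CLASSES)
  if (length(bad))
    stop("unknown land-use class(es) in config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(config$pollutants, POLLUTANTS)
  if (length(bad))
    stop("unknown pollutant(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  # traffic: nearest-road distances, buffered road sums, registered vehicles
  for (cl in config$road_classes)
    add(catalog_row(paste0("traffic.dist.", cl), "traffic", "road_distance",
                    road_class = cl))
  for (cl in config$road_classes)
    for (wt in config$road_weightings)
      for (r in config$traffic_radii)
        add(catalog_row(paste("traffic.roadsum", cl, wt, r, sep = "."),
                        "traffic", "buffer_road_sum", road_class = cl,
                        weighting = wt, radius = r))
  add(catalog_row("traffic.vehicles", "traffic", "vehicles"))
  # demographic characteristics
  for (a in config$census_attributes)
    for (r in config$nontraffic_radii)
      add(catalog_row(paste("demo", a, r, sep = "."),
                      "demographic", "areal_weighted_sum",
                      attribute = a, radius = r))
  # land use
  for (cc in config$landuse_classes)
    for (r in config$nontraffic_radii)
      add(catalog_row(paste("landuse", cc, r, sep = "."),
                      "land_use", "land_use_proportion",
                      class_code = cc, radius = r))
  # transportation facilities
  for (k in DEPOT_KINDS)
    add(catalog_row(paste0("transport.dist.", k), "transportation",
                    "depot_distance", target = k))
  # physical geography
  for (t in c("river", "coastline", "border"))
    add(catalog_row(paste0("physgeo.dist.", t), "physical_geography",
                    "physgeo_distance", target = t))
  # emissions
  for (p in config$pollutants)
    for (r in config$emission_radii)
      add(catalog_row(paste("emission", p, r, sep = "."),
                      "emissions", "emission_buffer_sum",
                      pollutant = p, radius = r))
  # vegetation
  for (m in c("annual_mean", "annual_min", "annual_max"))
    add(catalog_row(paste0("ndvi.", m), "vegetation", paste0("ndvi_", m)))
  add(catalog_row("ndvi.august_median", "vegetation", "ndvi_august_median"))
  # altitude
  add(catalog_row("alt.elevation", "altitude", "elevation"))
  for (rr in config$relative_elevation_rings)
    for (th in config$relative_elevation_thresholds)
      for (dir in c("above", "below"))
        add(catalog_row(paste("alt.relelev", dir, th, rr, sep = "."),
                        "altitude", "relative_elevation",
                        ring_radius = rr, threshold = th, direction = dir))
  cat <- do.call(rbind, rows)
  if (anyDuplicated(cat$name))
    stop("internal error: duplicate variable names in catalog", call. = FALSE)
  class(cat) <- c("geocov_catalog", "data.frame")
  cat
}

#' Registered vehicles for the district containing a site
#'
#' Finds the administrative district polygon containing each site and
#' returns the mean of that district's 12 monthly registration counts.
#' A site on a shared boundary resolves to the lowest district id; a site in
#' no district yields `NA` with a warning.
#'
#' @param sites a [monitoring_sites()] table.
#' @param districts an admin-district [polygon_layer()] whose `attrs` carry
#'   a `district_id` column.
#' @param monthly data frame with `district_id` plus exactly 12 monthly
#'   count columns.
#' @return numeric vector of annual mean counts, one per site.
#' @export
vehicles_for_site <- function(sites, districts, monthly) {
  stopifnot(inherits(districts, "geocov_polygons"))
  if (!"district_id" %in% names(districts$attrs))
    stop("districts layer needs a district_id attribute", call. = FALSE)
  if (!"district_id" %in% names(monthly))
    stop("monthly table needs a district_id column", call. = FALSE)
  mcols <- setdiff(names(monthly), "district_id")
  mcols <- mcols[vapply(monthly[mcols], is.numeric, logical(1))]
  if (length(mcols) != 12L)
    stop("monthly table must have exactly 12 numeric month columns, found ",
         length(mcols), call. = FALSE)
  means <- rowMeans(monthly[, mcols, drop = FALSE])
  names(means) <- as.character(monthly$district_id)
  ord <- order(districts$attrs$district_id)
  out <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    for (j in ord) {  # ascending district id => boundary ties resolve low
      if (point_in_polygon(sites$x[i], sites$y[i], districts$geoms[[j]])) {
        out[i] <- means[[as.character(districts$attrs$district_id[j])]]
        break
      }
    }
    if (is.na(out[i]))
      warning("site ", sites$site_id[i], " is in no district; vehicles NA",
              call. = FALSE)
  }
  out
}

#' Compute the full covariate table
#'
#' Evaluates every catalog variable at every site by dispatching to the
#' proper operation, returning the sites-by-variables matrix as a data frame
#' (column order = catalog order). Missing values (empty layers, failed
#' lookups) are `NA`, distinct from legitimate zeros (e.g. empty buffers).
#' Output is deterministic given identical inputs.
#'
#' The `layers` bundle is a named list; entries used per category:
#' `roads`, `urbanized` (traffic); `census` (demographic); `landcover`
#' (land use); `rail_station`/`subway_station`/`bus_stop`/`airport`/`port`
#' (transportation); `river`, `coastline`, `admin` (physical geography);
#' `emissions` (an [emission_grid_table()] or prebuilt cell polygons);
#' `ndvi_year`, `ndvi_years` (vegetation); `dem` (altitude); `districts` +
#' `vehicles_monthly` (registered vehicles); optional `width_table`.
#'
#' @param sites a [monitoring_sites()] table.
#' @param layers named list of loaded layers (see Details).
#' @param catalog a catalog from [build_default_catalog()].
#' @param config a configuration list, see [default_config()].
#' @return a `covariate_table` data frame: `site_id` column plus one numeric
#'   column per catalog variable; the long format is attached as attribute
#'   `"long"`.
#' @export
compute_covariates <- function(sites, layers, catalog = NULL,
                               config = default_config()) {
  if (is.null(catalog)) catalog <- build_default_catalog(config)
  scheme <- road_class_scheme(config$mr1_types, config$mr2_lane_threshold)
  nv <- config$buffer_vertices %||NA% DEFAULT_BUFFER_VERTICES
  wt_table <- layers$width_table %||NA% default_width_table()
  n <- nrow(sites)
  out <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)

  # cache cross-variable intermediates
  is_urban <- NULL
  if (!is.null(layers$roads))
    is_urban <- if (is.null(layers$urbanized)) rep(FALSE, nrow(layers$roads$attrs))
                else classify_urban(layers$roads, layers$urbanized)
  emission_polys <- NULL
  if (!is.null(layers$emissions)) {
    emission_polys <- if (inherits(layers$emissions, "geocov_emissions"))
      emission_cells_to_polygons(layers$emissions) else layers$emissions
  }
  border <- NULL
  road_mem <- if (!is.null(layers$roads))
    road_class_membership(layers$roads, scheme) else NULL
  ndvi_summary <- NULL
  vehicles <- NULL

  need_layer <- function(nm, var) {
    if (is.null(layers[[nm]]))
      stop("configuration error: variable '", var, "' needs layer '", nm, "'",
           call. = FALSE)
    layers[[nm]]
  }

  for (k in seq_len(nrow(catalog))) {
    def <- catalog[k, ]
    vals <- switch(def$op,
      road_distance = {
        roads <- need_layer("roads", def$name)
        sel <- which(road_mem[, def$road_class])
        sub <- list(geoms = roads$geoms[sel],
                    attrs = roads$attrs[sel, , drop = FALSE])
        class(sub) <- "geocov_roads"
        if (length(sel) == 0L) {
          warning("no segments in class ", def$road_class,
                  "; distance NA", call. = FALSE)
          rep(NA_real_, n)
        } else nearest_distance(sites, sub, target = def$road_class)$distance
      },
      buffer_road_sum = {
        roads <- need_layer("roads", def$name)
        buffer_road_sum(sites, def$radius, roads, def$road_class,
                        def$weighting, width_table = wt_table,
                        scheme = scheme, is_urban = is_urban)$value
      },
      vehicles = {
        if (is.null(vehicles)) {
          d <- need_layer("districts", def$name)
          m <- need_layer("vehicles_monthly", def$name)
          vehicles <- vehicles_for_site(sites, d, m)
        }
        vehicles
      },
      areal_weighted_sum = {
        census <- need_layer("census", def$name)
        if (!def$attribute %in% names(census$attrs))
          stop("configuration error: census attribute '", def$attribute,
               "' missing (variable '", def$name, "')", call. = FALSE)
        areal_weighted_sum(sites, def$radius, census, def$attribute,
                           n_vertices = nv)$value
      },
      land_use_proportion = {
        lc <- need_layer("landcover", def$name)
        land_use_proportion(sites, def$radius, lc, def$class_code,
                            n_vertices = nv)$value
      },
      depot_distance = {
        lay <- layers[[def$target]]
        if (is.null(lay)) {
          warning("no layer for depot '", def$target, "'; distance NA",
                  call. = FALSE)
          rep(NA_real_, n)
        } else {
          if (def$target == "port")
            lay <- filter_major_ports(lay, config$major_port_threshold)
          if (nrow(lay) == 0L) rep(NA_real_, n)
          else nearest_distance(sites, lay, target = def$target)$distance
        }
      },
      physgeo_distance = {
        if (def$target == "border") {
          if (is.null(border)) {
            admin <- need_layer("admin", def$name)
            border <- derive_border_line(admin,
                                         config$border_northern_fraction)
          }
          if (length(border) == 0L) rep(NA_real_, n)
          else nearest_distance(sites, border, target = "border")$distance
        } else {
          lay <- layers[[def$target]]
          if (is.null(lay)) {
            warning("no layer for '", def$target, "'; distance NA",
                    call. = FALSE)
            rep(NA_real_, n)
          } else nearest_distance(sites, lay, target = def$target)$distance
        }
      },
      emission_buffer_sum = {
        if (is.null(emission_polys))
          stop("configuration error: variable '", def$name,
               "' needs layer 'emissions'", call. = FALSE)
        emission_buffer_sum(sites, def$radius, emission_polys, def$pollutant,
                            n_vertices = nv)$value
      },
      ndvi_annual_mean = ,
      ndvi_annual_min = ,
      ndvi_annual_max = {
        if (is.null(ndvi_summary)) {
          st <- need_layer("ndvi_year", def$name)
          ndvi_summary <- ndvi_stack_summary(sites, st)
        }
        ndvi_summary[[sub("ndvi_", "", def$op)]]
      },
      ndvi_august_median = {
        stacks <- layers$ndvi_years %||NA% layers$ndvi_year
        if (is.null(stacks))
          stop("configuration error: variable '", def$name,
               "' needs layer 'ndvi_years'", call. = FALSE)
        ndvi_august_median(sites, stacks)
      },
      elevation = extract_cell_value(sites, need_layer("dem", def$name)),
      relative_elevation = {
        relative_elevation(sites, need_layer("dem", def$name),
                           def$ring_radius, def$threshold, def$direction,
                           ring_width = config$relative_elevation_ring_width
                           )$proportion
      },
      stop("unknown operation '", def$op, "' for variable '", def$name, "'",
           call. = FALSE)
    )
    out[[def$name]] <- vals
  }
  class(out) <- c("covariate_table", "data.frame")
  attr(out, "catalog") <- catalog
  out
}

#' Write a covariate table to CSV
#'
#' Wide format: one row per site, one column per variable. Long format:
#' columns `site_id`, `category`, `variable`, `radius_m`, `value`. Missing
#' values are written as empty cells, keeping them distinct from zeros.
#'
#' @param tab a `covariate_table` from [compute_covariates()].
#' @param path output CSV path.
#' @param format `"wide"` or `"long"`.
#' @return invisibly, `path`.
#' @export
write_covariates_csv <- function(tab, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  } else {
    catalog <- attr(tab, "catalog")
    vars <- setdiff(names(tab), "site_id")
    long <- do.call(rbind, lapply(vars, function(v) {
      i <- match(v, catalog$name)
      data.frame(site_id = tab$site_id,
                 category = if (is.na(i)) NA_character_ else catalog$category[i],
                 variable = v,
                 radius_m = if (is.na(i)) NA_real_ else catalog$radius[i],
                 value = tab[[v]], stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
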