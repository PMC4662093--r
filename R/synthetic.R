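# Seeded synthetic scenes with analytically known ground truth.
#
# The generator deliberately uses simple analytic geometries — grid-aligned
# roads, a rectangular census tessellation with uniform density, a half-plane
# land-cover mosaic, flat/ramp/half-plane DEM profiles — so that every
# covariate has a closed-form expected value and validation needs no oracle
# beyond arithmetic.

#' Synthetic scene specification
#'
#' @param seed integer RNG seed; the scene is a pure function of the spec.
#' @param extent scene rectangle `c(xmin, ymin, xmax, ymax)` in meters.
#' @param n_sites number of monitoring sites; site 1 always sits on the
#'   central road-grid node (ground-truth anchor), the rest are random
#'   interior points.
#' @param road_grid_spacing spacing of the orthogonal road grid in meters.
#' @param lane_choices lane counts sampled for road segments.
#' @param census_cell_size census tessellation cell edge in meters.
#' @param population_density uniform population density in persons/m^2.
#' @param landcover_classes classes of the two half-plane mosaic parts
#'   (west, east of the extent's vertical midline).
#' @param dem_profile `"flat"`, `"ramp"` (linear in x), `"half_plane"`
#'   (east 100 m higher) or `"random_field"`.
#' @param ndvi_constant constant byte value of NDVI composites, or `NA` for
#'   a seasonal sinusoid.
#' @param emission_constant per-cell total emission (split equally across
#'   point/line/area sources) for every pollutant.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(seed = 1L, extent = c(0, 0, 10000, 10000),
                       n_sites = 5L, road_grid_spacing = 2000,
                       lane_choices = c(2L, 4L, 8L),
                       census_cell_size = 1000,
                       population_density = 0.01,
                       landcover_classes = c("residential", "forest"),
                       dem_profile = c("flat", "ramp", "half_plane",
                                       "random_field"),
                       ndvi_constant = 150,
                       emission_constant = 10) {
  dem_profile <- match.arg(dem_profile)
  stopifnot(extent[3L] > extent[1L], extent[4L] > extent[2L],
            population_density >= 0, emission_constant >= 0,
            road_grid_spacing > 0, census_cell_size > 0)
  if (census_cell_size > min(extent[3L] - extent[1L], extent[4L] - extent[2L]))
    stop("census cell larger than the extent", call. = FALSE)
  structure(list(seed = as.integer(seed), extent = extent,
                 n_sites = as.integer(n_sites),
                 road_grid_spacing = road_grid_spacing,
                 lane_choices = as.integer(lane_choices),
                 census_cell_size = census_cell_size,
                 population_density = population_density,
                 landcover_classes = landcover_classes,
                 dem_profile = dem_profile,
                 ndvi_constant = ndvi_constant,
                 emission_constant = emission_constant),
            class = "scene_spec")
}

rect_poly <- function(x0, y0, x1, y1) {
  list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)))
}

#' Generate a complete synthetic scene
#'
#' Emits every layer type the covariate pipeline consumes, plus a
#' `ground_truth` record of closed-form expected values: areally weighted
#' population in a radius-r buffer equals `density * pi * r^2`; all-roads
#' length around the central grid node equals `4 r` (two perpendicular
#' chords); the west land-cover class proportion at the node is 0.5 (the
#' node lies on the mosaic split line); a flat DEM gives relative elevation
#' 0; a constant NDVI stack gives mean = min = max = the constant.
#'
#' @param spec a [scene_spec()].
#' @return a `geocov_scene` list of layers
#'   (`sites`, `roads`, `urbanized`, `census`, `landcover`, depots, `river`,
#'   `coastline`, `admin`, `districts`, `vehicles_monthly`, `emissions`,
#'   `ndvi_years`, `dem`) plus `ground_truth`, `config` and the `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  ex <- spec$extent
  w <- ex[3L] - ex[1L]
  h <- ex[4L] - ex[2L]
  cx_mid <- ex[1L] + w / 2
  cy_mid <- ex[2L] + h / 2
  sp <- spec$road_grid_spacing

  # --- road grid: verticals and horizontals through the extent center, so
  # the central node (= site 1) lies exactly on the land-cover split line ---
  xs <- sort(unique(c(seq(cx_mid, ex[1L], by = -sp),
                      seq(cx_mid, ex[3L], by = sp))))
  ys <- sort(unique(c(seq(cy_mid, ex[2L], by = -sp),
                      seq(cy_mid, ex[4L], by = sp))))
  geoms <- c(lapply(xs, function(x) rbind(c(x, ex[2L]), c(x, ex[4L]))),
             lapply(ys, function(y) rbind(c(ex[1L], y), c(ex[3L], y))))
  nr <- length(geoms)
  road_type <- sample(ROAD_TYPES, nr, replace = TRUE)
  # keep the two central-node roads plain local roads so the node ground
  # truth (4r of ALL-class road) is independent of random class draws
  vx_center <- which.min(abs(xs - cx_mid))
  hy_center <- which.min(abs(ys - cy_mid))
  road_type[c(vx_center, length(xs) + hy_center)] <- "district_road"
  lanes <- sample(spec$lane_choices, nr, replace = TRUE)
  lanes[c(vx_center, length(xs) + hy_center)] <- min(spec$lane_choices)
  is_highway <- road_type %in% c("national_highway", "metro_city_highway")
  speed <- ifelse(is_highway, 100, sample(c(50, 60, 80), nr, replace = TRUE))
  roads <- road_layer(geoms, road_type, lanes, speed, is_highway)

  # --- sites: site 1 on the central node, the rest random interior ---
  margin <- min(w, h) / 5
  node_x <- xs[vx_center]
  node_y <- ys[hy_center]
  sx <- c(node_x, stats::runif(spec$n_sites - 1L, ex[1L] + margin,
                               ex[3L] - margin))
  sy <- c(node_y, stats::runif(spec$n_sites - 1L, ex[2L] + margin,
                               ex[4L] - margin))
  sites <- monitoring_sites(paste0("s", seq_len(spec$n_sites)), sx, sy,
                            site_type = c("urban_roadside",
                                          rep("urban_background",
                                              spec$n_sites - 1L)))

  # --- census tessellation with uniform density ---
  cs <- spec$census_cell_size
  gx <- seq(ex[1L], ex[3L] - cs, by = cs)
  gy <- seq(ex[2L], ex[4L] - cs, by = cs)
  cells <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  cpolys <- lapply(seq_len(nrow(cells)), function(i) {
    rect_poly(cells$x[i], cells$y[i], cells$x[i] + cs, cells$y[i] + cs)
  })
  pop <- spec$population_density * cs * cs
  cfg <- default_config()
  cattrs <- data.frame(jipgegu_id = paste0("j", seq_len(nrow(cells))),
                       stringsAsFactors = FALSE)
  for (a in cfg$census_attributes) cattrs[[a]] <- pop
  census <- polygon_layer(cpolys, attrs = cattrs, layer_kind = "census")

  # --- land cover: vertical half-plane split at the midline ---
  landcover <- polygon_layer(
    list(rect_poly(ex[1L], ex[2L], cx_mid, ex[4L]),
         rect_poly(cx_mid, ex[2L], ex[3L], ex[4L])),
    attrs = data.frame(class_code = spec$landcover_classes,
                       stringsAsFactors = FALSE),
    layer_kind = "landcover")

  # --- urbanized area: western half ---
  urbanized <- polygon_layer(list(rect_poly(ex[1L], ex[2L], cx_mid, ex[4L])),
                             layer_kind = "urbanized_area")

  # --- depots ---
  rnd_pts <- function(n) data.frame(x = stats::runif(n, ex[1L], ex[3L]),
                                    y = stats::runif(n, ex[2L], ex[4L]))
  depots <- list(
    rail_station = point_layer(rnd_pts(4L), "rail_station"),
    subway_station = point_layer(rnd_pts(6L), "subway_station"),
    bus_stop = point_layer(rnd_pts(20L), "bus_stop"),
    airport = point_layer(rnd_pts(1L), "airport"))
  pdf_ <- rnd_pts(8L)
  pdf_$vessels_per_year <- c(20000, 15000, 12000, 9000, 8000, 5000, 2000, 500)
  depots$port <- point_layer(pdf_, "port")

  # --- physical geography ---
  river <- list(river1 = rbind(c(ex[1L], cy_mid + h / 4),
                               c(ex[3L], cy_mid + h / 4)))
  coastline <- list(coast1 = rbind(c(ex[1L], ex[2L]), c(ex[3L], ex[2L])))
  admin <- polygon_layer(cpolys,
                         attrs = data.frame(
                           feature_id = paste0("a", seq_len(nrow(cells))),
                           stringsAsFactors = FALSE),
                         layer_kind = "admin_district")

  # --- districts (quadrants) + monthly vehicle registrations ---
  districts <- polygon_layer(
    list(rect_poly(ex[1L], ex[2L], cx_mid, cy_mid),
         rect_poly(cx_mid, ex[2L], ex[3L], cy_mid),
         rect_poly(ex[1L], cy_mid, cx_mid, ex[4L]),
         rect_poly(cx_mid, cy_mid, ex[3L], ex[4L])),
    attrs = data.frame(district_id = c("d1", "d2", "d3", "d4"),
                       stringsAsFactors = FALSE),
    layer_kind = "admin_district")
  base <- round(stats::runif(4L, 50000, 200000))
  vm <- data.frame(district_id = c("d1", "d2", "d3", "d4"))
  for (m in 1:12)
    vm[[sprintf("m%02d", m)]] <- base + round(stats::rnorm(4L, 0, 100))

  # --- emission grid: constant field, split across the 3 source types ---
  ecs <- 1000
  egx <- seq(ex[1L], ex[3L] - ecs, by = ecs)
  egy <- seq(ex[2L], ex[4L] - ecs, by = ecs)
  eg <- expand.grid(corner_x = egx, corner_y = egy, KEEP.OUT.ATTRS = FALSE)
  rows <- expand.grid(i = seq_len(nrow(eg)), source = EMISSION_SOURCES,
                      pollutant = POLLUTANTS, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  emissions <- emission_grid_table(data.frame(
    corner_x = eg$corner_x[rows$i], corner_y = eg$corner_y[rows$i],
    source = rows$source, pollutant = rows$pollutant,
    estimate = spec$emission_constant / 3), cell_size = ecs)

  # --- NDVI stacks: 3 years x 36 composites on a ~428 m grid ---
  ncell <- 428
  nnc <- ceiling(w / ncell)
  nnr <- ceiling(h / ncell)
  mk_year <- function(year) {
    dates <- as.Date(paste0(year, "-01-05")) + 10 * (0:35)
    rasters <- lapply(seq_along(dates), function(k) {
      v <- if (is.na(spec$ndvi_constant))
        round(150 + 60 * sin(2 * pi * (k - 9) / 36)) else spec$ndvi_constant
      raster_grid(ex[1L], ex[2L], ncell,
                  matrix(v, nrow = nnr, ncol = nnc))
    })
    ndvi_stack(dates, rasters)
  }
  ndvi_years <- list(mk_year(2009), mk_year(2010), mk_year(2011))

  # --- DEM: 30 m cells, padded one cell beyond the extent so rings at the
  # scene boundary stay fully covered (as real elevation tiles would) ---
  dcs <- 30
  dnc <- ceiling(w / dcs) + 2L
  dnr <- ceiling(h / dcs) + 2L
  dem_ox <- ex[1L] - dcs
  dem_oy <- ex[2L] - dcs
  ccx <- dem_ox + (seq_len(dnc) - 0.5) * dcs
  ccy <- dem_oy + (seq_len(dnr) - 0.5) * dcs
  dem_vals <- switch(spec$dem_profile,
    flat = matrix(100, dnr, dnc),
    ramp = matrix(rep(100 + 0.02 * (ccx - ex[1L]), each = dnr), dnr, dnc),
    half_plane = matrix(rep(ifelse(ccx > cx_mid, 200, 100), each = dnr),
                        dnr, dnc),
    random_field = matrix(100 + stats::rnorm(dnr * dnc, 0, 30), dnr, dnc))
  dem <- raster_grid(dem_ox, dem_oy, dcs, dem_vals)

  gt <- list(
    population_in_buffer = function(r) spec$population_density * pi * r^2,
    node_road_length_km = function(r) 4 * r / 1000,
    landuse_west_at_node = 0.5,
    flat_dem_relative_elevation = if (spec$dem_profile == "flat") 0 else NULL,
    ndvi_constant = spec$ndvi_constant,
    emission_in_buffer = function(r) {
      spec$emission_constant * pi * r^2 / (ecs * ecs)
    },
    node_site_id = "s1")

  structure(list(sites = sites, roads = roads, urbanized = urbanized,
                 census = census, landcover = landcover,
                 rail_station = depots$rail_station,
                 subway_station = depots$subway_station,
                 bus_stop = depots$bus_stop, airport = depots$airport,
                 port = depots$port, river = river, coastline = coastline,
                 admin = admin, districts = districts, vehicles_monthly = vm,
                 emissions = emissions, ndvi_years = ndvi_years,
                 ndvi_year = ndvi_years[[2L]], dem = dem,
                 ground_truth = gt, config = cfg, spec = spec),
            class = "geocov_scene")
}

transform_xy <- function(m, kind, magnitude, center) {
  switch(kind,
    translate = sweep(m, 2L, magnitude, `+`),
    rotate = rotate_coords(m, magnitude, center[1L], center[2L]),
    rescale = m * magnitude)
}

#' Rigid-motion / scaling perturbation of a whole scene
#'
#' Applies one coherent transform to all vector layers and sites, for
#' invariance testing: `translate` (magnitude = `c(dx, dy)`), `rotate`
#' (degrees, about the extent center) or `rescale` (factor, about the
#' origin). Rasters follow exactly for translation and rescaling; rotation
#' rotates the grids only for multiples of 90 degrees (otherwise rasters are
#' dropped from the perturbed scene with a warning, since a regular grid
#' cannot represent an oblique rotation).
#'
#' @param scene a `geocov_scene`.
#' @param kind `"translate"`, `"rotate"` or `"rescale"`.
#' @param magnitude see Description.
#' @return the transformed `geocov_scene`.
#' @export
perturb_scene <- function(scene, kind = c("translate", "rotate", "rescale"),
                          magnitude) {
  kind <- match.arg(kind)
  ex <- scene$spec$extent
  center <- c((ex[1L] + ex[3L]) / 2, (ex[2L] + ex[4L]) / 2)
  tx <- function(m) transform_xy(as.matrix(m), kind, magnitude, center)

  s <- scene
  xy <- tx(cbind(s$sites$x, s$sites$y))
  s$sites$x <- xy[, 1L]
  s$sites$y <- xy[, 2L]
  s$roads$geoms <- lapply(s$roads$geoms, tx)
  for (nm in c("urbanized", "census", "landcover", "admin", "districts")) {
    s[[nm]]$geoms <- lapply(s[[nm]]$geoms, function(p) {
      normalize_polygon(lapply(p, tx))
    })
    s[[nm]]$areas <- vapply(s[[nm]]$geoms, polygon_area, numeric(1))
  }
  for (nm in c("rail_station", "subway_station", "bus_stop", "airport",
               "port")) {
    xy <- tx(cbind(s[[nm]]$x, s[[nm]]$y))
    s[[nm]]$x <- xy[, 1L]
    s[[nm]]$y <- xy[, 2L]
  }
  s$river <- lapply(s$river, tx)
  s$coastline <- lapply(s$coastline, tx)

  tx_raster <- function(r) {
    if (kind == "translate") {
      r$origin_x <- r$origin_x + magnitude[1L]
      r$origin_y <- r$origin_y + magnitude[2L]
      r
    } else if (kind == "rescale") {
      r$origin_x <- r$origin_x * magnitude
      r$origin_y <- r$origin_y * magnitude
      r$cell_size <- r$cell_size * magnitude
      r
    } else if (magnitude %% 90 == 0) {
      turns <- (magnitude / 90) %% 4
      v <- r$values
      ox <- r$origin_x
      oy <- r$origin_y
      for (t in seq_len(turns)) {
        # rotate the grid's bbox corners 90 deg CCW about the scene center,
        # then re-derive the lower-left origin
        crn <- rotate_coords(rbind(c(ox, oy),
                                   c(ox + ncol(v) * r$cell_size,
                                     oy + nrow(v) * r$cell_size)),
                             90, center[1L], center[2L])
        ox <- min(crn[, 1L])
        oy <- min(crn[, 2L])
        # CCW turn: new[r2, c2] = old[r, c] with r2 = c, c2 = nrow - r + 1
        v <- t(v)[, rev(seq_len(nrow(v))), drop = FALSE]
      }
      r$origin_x <- ox
      r$origin_y <- oy
      r$values <- v
      r$n_rows <- nrow(v)
      r$n_cols <- ncol(v)
      r
    } else {
      NULL
    }
  }
  dem2 <- tx_raster(s$dem)
  if (is.null(dem2)) {
    warning("non-right-angle rotation: rasters dropped from perturbed scene",
            call. = FALSE)
    s$dem <- NULL
    s$ndvi_years <- NULL
    s$ndvi_year <- NULL
  } else {
    s$dem <- dem2
    s$ndvi_years <- lapply(s$ndvi_years, function(st) {
      st$rasters <- lapply(st$rasters, tx_raster)
      st
    })
    s$ndvi_year <- s$ndvi_years[[2L]]
  }
  if (kind == "translate") {
    s$spec$extent <- ex + c(magnitude, magnitude)
    em <- as.data.frame(s$emissions)
    em$corner_x <- em$corner_x + magnitude[1L]
    em$corner_y <- em$corner_y + magnitude[2L]
    s$emissions <- emission_grid_table(em, attr(scene$emissions, "cell_size"))
  } else if (kind == "rescale") {
    s$spec$extent <- ex * magnitude
    em <- as.data.frame(s$emissions)
    em$corner_x <- em$corner_x * magnitude
    em$corner_y <- em$corner_y * magnitude
    s$emissions <- emission_grid_table(
      em, attr(scene$emissions, "cell_size") * magnitude)
  }
  s
}

#' Write a scene to a directory of standard input files
#'
#' Writes every layer in the pipeline's plain-text interchange formats
#' (WKT-geometry CSVs, ASCII-grid rasters, CSV tables, NDVI manifests) plus
#' a ready-to-use `config.yaml`, so the full CLI path can be exercised.
#' Output is byte-deterministic for a fixed spec.
#'
#' @param scene a `geocov_scene`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_sites_csv(scene$sites, p("sites.csv"))
  write_vector_layer(scene$roads, p("roads.csv"))
  for (nm in c("urbanized", "census", "landcover", "admin", "districts"))
    write_vector_layer(scene[[nm]], p(paste0(nm, ".csv")))
  for (nm in c("rail_station", "subway_station", "bus_stop", "airport",
               "port"))
    write_vector_layer(scene[[nm]], p(paste0(nm, ".csv")))
  line_layer_csv <- function(lines, path) {
    df <- data.frame(feature_id = names(lines),
                     wkt = vapply(lines, function(l) {
                       write_wkt("LINESTRING", l)
                     }, character(1)), stringsAsFactors = FALSE)
    write_csv_with_crs(df, path)
  }
  line_layer_csv(scene$river, p("river.csv"))
  line_layer_csv(scene$coastline, p("coastline.csv"))
  utils::write.csv(scene$vehicles_monthly, p("vehicles_monthly.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(scene$emissions), p("emissions.csv"),
                   row.names = FALSE)
  for (yi in seq_along(scene$ndvi_years)) {
    st <- scene$ndvi_years[[yi]]
    ydir <- p(paste0("ndvi_", format(st$dates[1L], "%Y")))
    dir.create(ydir, showWarnings = FALSE)
    paths <- sprintf("c%02d.asc", seq_along(st$rasters))
    for (k in seq_along(st$rasters))
      write_ascii_grid(st$rasters[[k]], file.path(ydir, paths[k]))
    utils::write.csv(data.frame(date = st$dates, path = paths),
                     file.path(ydir, "manifest.csv"), row.names = FALSE)
  }
  write_ascii_grid(scene$dem, p("dem.asc"))
  cfg <- scene$config
  cfg$layers <- list(
    sites = "sites.csv", roads = "roads.csv", urbanized = "urbanized.csv",
    census = "census.csv", landcover = "landcover.csv", admin = "admin.csv",
    districts = "districts.csv", vehicles_monthly = "vehicles_monthly.csv",
    rail_station = "rail_station.csv", subway_station = "subway_station.csv",
    bus_stop = "bus_stop.csv", airport = "airport.csv", port = "port.csv",
    river = "river.csv", coastline = "coastline.csv",
    emissions = "emissions.csv",
    ndvi_manifests = file.path(paste0("ndvi_", 2009:2011), "manifest.csv"),
    ndvi_current_year = 2L, dem = "dem.asc")
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}

#' Load a layers bundle from a scene directory / config file
#'
#' Reads the `config.yaml` written by [write_scene()] (or a hand-written one
#' with the same shape: a `layers` map of relative paths plus the
#' configuration entries of [default_config()]) and loads every referenced
#' layer.
#'
#' @param config_path path to the YAML configuration file.
#' @return list with `sites`, `layers` and `config`.
#' @export
read_layers_bundle <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(config_path)
  lp <- function(x) file.path(base, x)
  ly <- cfg$layers
  layers <- list()
  read_line_layer <- function(path) {
    df <- read_csv_with_crs(path)
    assert_projected_crs(attr(df, "crs"))
    out <- lapply(df$wkt, function(s) parse_wkt(s)$coords)
    names(out) <- df$feature_id
    out
  }
  if (!is.null(ly$roads))
    layers$roads <- load_vector_layer(lp(ly$roads), "road")
  for (nm in c("urbanized", "census", "landcover", "admin", "districts")) {
    kind <- switch(nm, urbanized = "urbanized_area",
                   census = "census", landcover = "landcover",
                   admin = "admin_district", districts = "admin_district")
    if (!is.null(ly[[nm]]))
      layers[[nm]] <- load_vector_layer(lp(ly[[nm]]), kind)
  }
  for (nm in POINT_KINDS)
    if (!is.null(ly[[nm]]))
      layers[[nm]] <- load_vector_layer(lp(ly[[nm]]), nm)
  if (!is.null(ly$river)) layers$river <- read_line_layer(lp(ly$river))
  if (!is.null(ly$coastline))
    layers$coastline <- read_line_layer(lp(ly$coastline))
  if (!is.null(ly$vehicles_monthly))
    layers$vehicles_monthly <- utils::read.csv(lp(ly$vehicles_monthly),
                                               stringsAsFactors = FALSE)
  if (!is.null(ly$emissions))
    layers$emissions <- read_emission_table(lp(ly$emissions))
  if (!is.null(ly$ndvi_manifests)) {
    layers$ndvi_years <- lapply(ly$ndvi_manifests, function(m) {
      read_ndvi_stack(lp(m))
    })
    cur <- ly$ndvi_current_year %||NA% 1L
    layers$ndvi_year <- layers$ndvi_years[[cur]]
  }
  if (!is.null(ly$dem)) layers$dem <- read_ascii_grid(lp(ly$dem))
  if (!is.null(ly$width_table))
    layers$width_table <- read_width_table(lp(ly$width_table))
  sites <- if (!is.null(ly$sites)) read_sites_csv(lp(ly$sites)) else NULL
  cfg$layers <- NULL
  config <- utils::modifyList(default_config(), cfg)
  list(sites = sites, layers = layers, config = config)
}
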