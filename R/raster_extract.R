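# Raster extraction: vegetation-index (NDVI) point summaries from composite
# stacks, and absolute/relative elevation from a DEM.

#' Normalized difference vegetation index from band reflectances
#'
#' `(nir - red) / (nir + red)`, the standard index contrasting near-infrared
#' and visible-red reflectance; vectorized. Undefined where `nir + red == 0`
#' (returns `NA`). Distribution-ready composite stacks usually carry the
#' index rescaled to bytes 0-255 instead; see [ndvi_stack_summary()].
#'
#' @param nir,red band reflectances, >= 0.
#' @return index values in [-1, 1]; `NA` where undefined.
#' @examples
#' ndvi_from_bands(0.6, 0.2)  # 0.5
#' @export
ndvi_from_bands <- function(nir, red) {
  s <- nir + red
  ifelse(s == 0, NA_real_, (nir - red) / s)
}

# half-open cell lookup: cell i covers [origin + (i-1)*c, origin + i*c)
cell_index <- function(coord, origin, cell_size, n) {
  i <- floor((coord - origin) / cell_size) + 1
  i[i < 1 | i > n] <- NA
  as.integer(i)
}

#' Extract raster cell values at sites
#'
#' Returns the value of the cell whose half-open footprint contains each
#' site — no interpolation; a site on a shared cell edge belongs to the cell
#' on the +x/+y side. Sites outside the extent and nodata cells yield `NA`.
#'
#' @param sites a [monitoring_sites()] table.
#' @param raster a [raster_grid()].
#' @return numeric vector of cell values, one per site.
#' @export
extract_cell_value <- function(sites, raster) {
  col <- cell_index(sites$x, raster$origin_x, raster$cell_size, raster$n_cols)
  row <- cell_index(sites$y, raster$origin_y, raster$cell_size, raster$n_rows)
  out <- rep(NA_real_, nrow(sites))
  ok <- !is.na(col) & !is.na(row)
  out[ok] <- raster$values[cbind(row[ok], col[ok])]
  out
}

#' Annual NDVI summary at sites
#'
#' Extracts the site's cell value from every composite in the stack, drops
#' nodata values, and summarizes with mean, minimum and maximum. A site with
#' no valid composite gets an all-`NA` summary. Values are reported on the
#' stack's native scale (byte 0-255 for distribution composites).
#'
#' @param sites a [monitoring_sites()] table.
#' @param stack an [ndvi_stack()].
#' @return data frame with `site_id`, `annual_mean`, `annual_min`,
#'   `annual_max`.
#' @export
ndvi_stack_summary <- function(sites, stack) {
  stopifnot(inherits(stack, "geocov_ndvi_stack"))
  vals <- vapply(stack$rasters, function(r) extract_cell_value(sites, r),
                 numeric(nrow(sites)))
  vals <- matrix(vals, nrow = nrow(sites))  # sites x composites
  summ <- t(apply(vals, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(v), min(v), max(v))
  }))
  data.frame(site_id = sites$site_id, annual_mean = summ[, 1L],
             annual_min = summ[, 2L], annual_max = summ[, 3L],
             stringsAsFactors = FALSE)
}

#' Pooled August NDVI median at sites
#'
#' Pools the site's cell values from all August-dated composites across the
#' supplied yearly stacks (previous, current and following year, typically)
#' and returns the median — capturing peak-vegetation conditions. Even
#' pooled counts use the mean-of-central-pair median convention.
#'
#' @param sites a [monitoring_sites()] table.
#' @param stacks_by_year list of [ndvi_stack()] objects.
#' @param august_selector predicate on `Date` vectors choosing the pooled
#'   composites; defaults to calendar-August dates.
#' @return numeric vector of medians, one per site (`NA` where no August
#'   composite has data).
#' @export
ndvi_august_median <- function(sites, stacks_by_year,
                               august_selector = function(d) {
                                 format(d, "%m") == "08"
                               }) {
  if (inherits(stacks_by_year, "geocov_ndvi_stack"))
    stacks_by_year <- list(stacks_by_year)
  pooled <- vector("list", nrow(sites))
  any_august <- FALSE
  for (stack in stacks_by_year) {
    sel <- which(august_selector(stack$dates))
    if (length(sel)) any_august <- TRUE
    for (k in sel) {
      v <- extract_cell_value(sites, stack$rasters[[k]])
      for (i in seq_len(nrow(sites)))
        pooled[[i]] <- c(pooled[[i]], v[i])
    }
  }
  if (!any_august) {
    warning("no August composites in any stack; medians are NA", call. = FALSE)
    return(rep(NA_real_, nrow(sites)))
  }
  vapply(pooled, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
}

#' Relative elevation on a concentric ring
#'
#' Compares the site's own DEM cell elevation with the cells whose centers
#' fall on a thin annulus (default 30 m total width) at a nominal radius
#' (1 or 5 km, conventionally). Reports the percentage of ring cells whose
#' elevation exceeds the site's by more than `threshold`
#' (`direction = "above"`) or falls short by more than `threshold`
#' (`"below"`). Adding a constant to the whole DEM leaves the result
#' unchanged. A ring extending beyond the raster uses the available cells
#' with a warning; a ring with no cells yields `NA`.
#'
#' @param sites a [monitoring_sites()] table.
#' @param dem a [raster_grid()] of elevations (meters).
#' @param ring_radius nominal ring radius in meters.
#' @param threshold elevation-difference threshold in meters (20 or 50,
#'   conventionally).
#' @param direction `"above"` or `"below"`.
#' @param ring_width total annulus width in meters (default 30): cells with
#'   center distance in `[ring_radius - ring_width/2, ring_radius +
#'   ring_width/2]` belong to the ring.
#' @return data frame with `site_id`, `ring_radius`, `threshold`,
#'   `direction`, `proportion` (percent in [0, 100]).
#' @export
relative_elevation <- function(sites, dem, ring_radius, threshold,
                               direction = c("above", "below"),
                               ring_width = 30) {
  direction <- match.arg(direction)
  stopifnot(inherits(dem, "geocov_raster"), ring_radius > 0, ring_width > 0)
  e0 <- extract_cell_value(sites, dem)
  r_out <- ring_radius + ring_width / 2
  r_in <- ring_radius - ring_width / 2
  cs <- dem$cell_size
  prop <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (is.na(e0[i])) next
    cx <- sites$x[i]
    cy <- sites$y[i]
    cmin <- max(1L, cell_index(cx - r_out, dem$origin_x, cs, dem$n_cols) %||% 1L)
    cmax <- min(dem$n_cols,
                cell_index(cx + r_out, dem$origin_x, cs, dem$n_cols) %||% dem$n_cols)
    rmin <- max(1L, cell_index(cy - r_out, dem$origin_y, cs, dem$n_rows) %||% 1L)
    rmax <- min(dem$n_rows,
                cell_index(cy + r_out, dem$origin_y, cs, dem$n_rows) %||% dem$n_rows)
    if (cx - r_out < dem$origin_x || cy - r_out < dem$origin_y ||
        cx + r_out > dem$origin_x + dem$n_cols * cs ||
        cy + r_out > dem$origin_y + dem$n_rows * cs)
      warning("ring at site ", sites$site_id[i],
              " extends beyond the DEM; using available cells", call. = FALSE)
    cols <- cmin:cmax
    rows <- rmin:rmax
    ccx <- dem$origin_x + (cols - 0.5) * cs
    ccy <- dem$origin_y + (rows - 0.5) * cs
    d2 <- outer((ccy - cy)^2, (ccx - cx)^2, `+`)  # rows x cols
    on_ring <- d2 >= r_in^2 & d2 <= r_out^2
    if (!any(on_ring)) next
    elev <- dem$values[rows, cols, drop = FALSE][on_ring]
    elev <- elev[!is.na(elev)]
    if (length(elev) == 0L) next
    hit <- if (direction == "above") elev > e0[i] + threshold
           else elev < e0[i] - threshold
    prop[i] <- 100 * sum(hit) / length(elev)
  }
  data.frame(site_id = sites$site_id, ring_radius = ring_radius,
             threshold = threshold, direction = direction,
             proportion = prop, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
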