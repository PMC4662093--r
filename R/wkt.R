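# Minimal WKT reader/writer for the geometry types the package consumes.
# Supported: POINT, LINESTRING, POLYGON, MULTILINESTRING, MULTIPOLYGON.
# Used by the CSV vector-layer interchange format (column `wkt`).

#' Parse a WKT geometry string
#'
#' Returns a list with elements `type` (one of `"POINT"`, `"LINESTRING"`,
#' `"POLYGON"`, `"MULTILINESTRING"`, `"MULTIPOLYGON"`) and `coords`:
#' a length-2 numeric vector for points, a coordinate matrix for linestrings,
#' a list of ring matrices for polygons (exterior first), a list of matrices
#' for multilinestrings, and a list of polygons for multipolygons.
#'
#' @param s a single WKT string.
#' @return a list with `type` and `coords` (see Details).
#' @examples
#' parse_wkt("LINESTRING (0 0, 10 0)")
#' @export
parse_wkt <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- trimws(s)
  type <- toupper(sub("^\\s*([A-Za-z]+).*$", "\\1", s))
  body <- trimws(sub("^\\s*[A-Za-z]+\\s*", "", s))
  if (toupper(body) == "EMPTY") return(list(type = type, coords = NULL))
  strip1 <- function(x) {
    x <- trimws(x)
    if (!startsWith(x, "(") || !endsWith(x, ")"))
      stop("malformed WKT: ", s, call. = FALSE)
    substr(x, 2L, nchar(x) - 1L)
  }
  coords_of <- function(x) {
    pts <- strsplit(trimws(x), "\\s*,\\s*")[[1L]]
    m <- t(vapply(pts, function(p) {
      as.numeric(strsplit(trimws(p), "\\s+")[[1L]][1:2])
    }, numeric(2)))
    dimnames(m) <- NULL
    m
  }
  # split a "(...),(...)" list at top-level commas
  split_parts <- function(x) {
    depth <- 0L
    cut <- integer(0)
    chars <- strsplit(x, "")[[1L]]
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "(") depth <- depth + 1L
      else if (ch == ")") depth <- depth - 1L
      else if (ch == "," && depth == 0L) cut <- c(cut, i)
    }
    starts <- c(1L, cut + 1L)
    ends <- c(cut - 1L, nchar(x))
    mapply(function(a, b) trimws(substr(x, a, b)), starts, ends,
           USE.NAMES = FALSE)
  }
  coords <- switch(type,
    POINT = as.numeric(coords_of(strip1(body))[1L, ]),
    LINESTRING = coords_of(strip1(body)),
    POLYGON = lapply(split_parts(strip1(body)),
                     function(p) coords_of(strip1(p))),
    MULTILINESTRING = lapply(split_parts(strip1(body)),
                             function(p) coords_of(strip1(p))),
    MULTIPOLYGON = lapply(split_parts(strip1(body)), function(pg) {
      lapply(split_parts(strip1(pg)), function(p) coords_of(strip1(p)))
    }),
    stop("unsupported WKT type: ", type, call. = FALSE)
  )
  list(type = type, coords = coords)
}

fmt_coords <- function(m) {
  paste(apply(m, 1L, function(r) {
    paste(format(r, scientific = FALSE, trim = TRUE, digits = 15),
          collapse = " ")
  }), collapse = ", ")
}

close_ring_mat <- function(r) {
  if (!all(r[1L, ] == r[nrow(r), ])) r <- rbind(r, r[1L, , drop = FALSE])
  r
}

#' Serialize a geometry to WKT
#'
#' Inverse of [parse_wkt()]. Polygon rings are closed on output.
#'
#' @param type geometry type string.
#' @param coords coordinates in the representation produced by [parse_wkt()].
#' @return a WKT string.
#' @export
write_wkt <- function(type, coords) {
  type <- toupper(type)
  switch(type,
    POINT = sprintf("POINT (%s)", fmt_coords(matrix(coords, nrow = 1L))),
    LINESTRING = sprintf("LINESTRING (%s)", fmt_coords(coords)),
    POLYGON = sprintf("POLYGON (%s)", paste(vapply(coords, function(r) {
      sprintf("(%s)", fmt_coords(close_ring_mat(r)))
    }, character(1)), collapse = ", ")),
    MULTILINESTRING = sprintf("MULTILINESTRING (%s)",
      paste(vapply(coords, function(l) sprintf("(%s)", fmt_coords(l)),
                   character(1)), collapse = ", ")),
    MULTIPOLYGON = sprintf("MULTIPOLYGON (%s)",
      paste(vapply(coords, function(pg) {
        sprintf("(%s)", paste(vapply(pg, function(r) {
          sprintf("(%s)", fmt_coords(close_ring_mat(r)))
        }, character(1)), collapse = ", "))
      }, character(1)), collapse = ", ")),
    stop("unsupported WKT type: ", type, call. = FALSE)
  )
}
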