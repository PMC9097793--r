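#' Polygon sets
#'
#' Planar polygons in WGS84 lon/lat, stored as a list of polygons, each a
#' list of rings (two-column matrices, lon then lat). Ring membership is
#' resolved with the even-odd rule, so a second ring inside an outer ring
#' acts as a hole. This lightweight container backs study boundaries and
#' protected-area overlays.
#'
#' @param polygons list of polygons; each polygon a list of two-column
#'   matrices, or a single matrix (taken as one outer ring).
#' @return object of class `polygon_set`.
#' @examples
#' ps <- polygon_set(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
#' point_in_polygons(ps, cbind(0.5, 0.5))
#' @export
polygon_set <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(list(polygons))
  polys <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2L || nrow(ring) < 3L)
        .stopf("each ring needs >= 3 vertices and 2 columns (lon, lat)")
      storage.mode(ring) <- "double"
      if (any(!is.finite(ring))) .stopf("non-finite polygon coordinate")
      # drop an explicit closing vertex; closure is implicit
      n <- nrow(ring)
      if (all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
      if (nrow(ring) < 3L) .stopf("degenerate ring after closing")
      unname(ring)
    })
  })
  structure(list(polygons = polys), class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  nr <- sum(vapply(x$polygons, length, 1L))
  cat(sprintf("polygon_set: %d polygon(s), %d ring(s)\n",
              length(x$polygons), nr))
  bb <- ps_bbox(x)
  cat(sprintf("  bbox: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              bb["west"], bb["east"], bb["south"], bb["north"]))
  invisible(x)
}

#' Axis-aligned rectangle polygon
#'
#' @param west,south,east,north rectangle edges in decimal degrees.
#' @return a `polygon_set` with one rectangular polygon.
#' @export
ps_rect <- function(west, south, east, north) {
  if (!(east > west && north > south)) .stopf("empty rectangle")
  polygon_set(cbind(c(west, east, east, west),
                    c(south, south, north, north)))
}

#' Bounding box of a polygon set
#'
#' @param ps a `polygon_set`.
#' @return named numeric vector (west, east, south, north).
#' @export
ps_bbox <- function(ps) {
  stopifnot(inherits(ps, "polygon_set"))
  xy <- do.call(rbind, unlist(ps$polygons, recursive = FALSE))
  c(west = min(xy[, 1L]), east = max(xy[, 1L]),
    south = min(xy[, 2L]), north = max(xy[, 2L]))
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized ray-cast over all rings of all polygons in the set; a point is
#' inside when an eastward ray crosses ring edges an odd number of times.
#' Points exactly on an edge are resolved arbitrarily (half-open rule).
#'
#' @param ps a `polygon_set`.
#' @param pts two-column matrix (lon, lat).
#' @return logical vector, one entry per point.
#' @export
point_in_polygons <- function(ps, pts) {
  stopifnot(inherits(ps, "polygon_set"))
  pts <- matrix(as.numeric(pts), ncol = 2L)
  px <- pts[, 1L]; py <- pts[, 2L]
  inside <- rep(FALSE, length(px))
  for (poly in ps$polygons) {
    for (ring in poly) {
      n <- nrow(ring)
      x1 <- ring[, 1L]; y1 <- ring[, 2L]
      idx2 <- c(2:n, 1L)
      x2 <- ring[idx2, 1L]; y2 <- ring[idx2, 2L]
      for (e in seq_len(n)) {
        crosses <- ((y1[e] > py) != (y2[e] > py))
        if (any(crosses)) {
          xint <- (x2[e] - x1[e]) * (py - y1[e]) / (y2[e] - y1[e]) + x1[e]
          inside <- xor(inside, crosses & (px < xint))
        }
      }
    }
  }
  inside
}

#' Read polygons from GeoJSON
#'
#' Accepts FeatureCollection, Feature, Polygon and MultiPolygon objects;
#' only polygonal geometry is kept.
#'
#' @param path path to a GeoJSON file.
#' @return a `polygon_set` (empty set allowed).
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) .stopf("GeoJSON file not found: %s", path)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- list()
  collect <- function(obj) {
    if (is.null(obj$type)) return()
    switch(obj$type,
      FeatureCollection = for (f in obj$features) collect(f),
      Feature = collect(obj$geometry),
      Polygon = geoms[[length(geoms) + 1L]] <<- obj$coordinates,
      MultiPolygon = for (p in obj$coordinates)
        geoms[[length(geoms) + 1L]] <<- p,
      invisible(NULL))
  }
  collect(g)
  if (!length(geoms))
    return(structure(list(polygons = list()), class = "polygon_set"))
  polys <- lapply(geoms, function(rings) {
    lapply(rings, function(ring) {
      do.call(rbind, lapply(ring, function(v) c(v[[1L]], v[[2L]])))
    })
  })
  polygon_set(polys)
}

#' Write polygons to GeoJSON
#'
#' Each polygon becomes one Feature with a Polygon geometry (rings closed on
#' output). Optional per-polygon properties are attached from a data frame.
#'
#' @param ps a `polygon_set`.
#' @param path output path.
#' @param properties optional data frame with one row per polygon.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(ps, path, properties = NULL) {
  stopifnot(inherits(ps, "polygon_set"))
  feats <- lapply(seq_along(ps$polygons), function(i) {
    rings <- lapply(ps$polygons[[i]], function(ring) {
      ring <- rbind(ring, ring[1L, ])
      lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1L], ring[r, 2L]))
    })
    props <- if (is.null(properties)) structure(list(), names = character())
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
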