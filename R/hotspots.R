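#' Landscape-mean diversity threshold
#'
#' The hotspot membership cut on the diversity scale:
#' `mean + z_threshold * sd`, mean and SD taken over the masked-in cells
#' (population SD, dividing by the cell count).
#'
#' @param surface a `gl_surface`.
#' @param z_threshold standard-deviation multiple (default 1.5).
#' @return threshold value on the surface's scale.
#' @export
threshold_value <- function(surface, z_threshold = 1.5) {
  stopifnot(inherits(surface, "gl_surface"))
  v <- surface$values[surface$grid$mask]
  if (length(v) < 2L) .stopf("need >= 2 masked-in cells")
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) .stopf("constant surface: threshold undefined (zero SD)")
  mean(v) + z_threshold * s
}

#' Detect genetic-diversity hotspots
#'
#' Flags cells whose value exceeds the landscape mean by more than
#' `z_threshold` standard deviations, groups flagged cells into connected
#' components (8- or 4-connectivity), and labels components A, B, ... in
#' descending order of area.
#'
#' @param surface a `gl_surface` (typically the combined diversity surface).
#' @param z_threshold standard-deviation multiple (default 1.5).
#' @param connectivity 8 (diagonals merge, default) or 4.
#' @return object of class `hotspot_set`: list with `hotspots` (each with
#'   `label`, `cells` (row/col matrix), `area_km2`, `centroid`), the
#'   `threshold`, landscape `mean` and `sd`, and the source grid. A constant
#'   surface yields an empty set flagged `degenerate`.
#' @export
detect_hotspots <- function(surface, z_threshold = 1.5, connectivity = 8L) {
  stopifnot(inherits(surface, "gl_surface"))
  if (!connectivity %in% c(4L, 8L)) .stopf("connectivity must be 4 or 8")
  g <- surface$grid
  v <- surface$values[g$mask]
  if (length(v) < 2L) .stopf("need >= 2 masked-in cells")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  empty <- structure(list(hotspots = list(), threshold = NA_real_,
                          mean = m, sd = s, z = z_threshold, grid = g),
                     class = "hotspot_set")
  if (s == 0) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  thr <- m + z_threshold * s
  empty$threshold <- thr
  flag <- !is.na(surface$values) & surface$values > thr
  cells <- which(flag, arr.ind = TRUE)
  if (!nrow(cells)) return(empty)
  comp <- .grid_components(cells, connectivity)
  areas <- cell_areas(g)
  ctr_lon <- g$west + (cells[, 2L] - 0.5) * g$res
  ctr_lat <- g$north - (cells[, 1L] - 0.5) * g$res
  hs <- lapply(split(seq_len(nrow(cells)), comp), function(ii) {
    cc <- cells[ii, , drop = FALSE]
    a <- sum(areas[cc])
    list(cells = unname(cc), area_km2 = a,
         centroid = c(lon = mean(ctr_lon[ii]), lat = mean(ctr_lat[ii])))
  })
  hs <- hs[order(-vapply(hs, `[[`, 1, "area_km2"))]
  lab <- .letter_labels(length(hs))
  for (i in seq_along(hs)) hs[[i]]$label <- lab[i]
  empty$hotspots <- unname(hs)
  empty
}

# connected components of flagged grid cells
.grid_components <- function(cells, connectivity) {
  n <- nrow(cells)
  if (n == 1L) return(1L)
  key <- paste(cells[, 1L], cells[, 2L])
  lut <- stats::setNames(seq_len(n), key)
  offs <- if (connectivity == 8L) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- paste(cells[, 1L] + offs[o, 1L], cells[, 2L] + offs[o, 2L])
    hit <- !is.na(lut[nb])
    from <- c(from, which(hit)); to <- c(to, unname(lut[nb[hit]]))
  }
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
  igraph::components(gr)$membership[seq_len(n)]
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("hotspot_set: %d hotspot(s) at z > %.2f (threshold %.4f; mean %.4f, sd %.4f)\n",
              length(x$hotspots), x$z, x$threshold, x$mean, x$sd))
  for (h in x$hotspots)
    cat(sprintf("  %s: %d cells, %.1f km2, centroid (%.3f, %.3f)\n",
                h$label, nrow(h$cells), h$area_km2,
                h$centroid["lon"], h$centroid["lat"]))
  invisible(x)
}

#' Hotspot summary table
#'
#' @param hotspots a `hotspot_set`.
#' @return data frame: label, n_cells, area_km2, centroid_lon, centroid_lat.
#' @export
hotspot_table <- function(hotspots) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  if (!length(hotspots$hotspots))
    return(data.frame(label = character(), n_cells = integer(),
                      area_km2 = numeric(), centroid_lon = numeric(),
                      centroid_lat = numeric()))
  do.call(rbind, lapply(hotspots$hotspots, function(h)
    data.frame(label = h$label, n_cells = nrow(h$cells),
               area_km2 = h$area_km2, centroid_lon = unname(h$centroid["lon"]),
               centroid_lat = unname(h$centroid["lat"]))))
}

#' Protected-area overlap of hotspots
#'
#' A hotspot cell counts as protected when its center lies inside any
#' protected-area polygon; the outside fraction is the unprotected share of
#' total hotspot area (area-weighted by cell).
#'
#' @param hotspots a `hotspot_set` with at least one hotspot.
#' @param protected_areas a `polygon_set` (may be empty).
#' @param grid the hotspot grid (defaults to the set's own grid).
#' @return list with `outside_fraction` in `[0, 1]` and `per_hotspot`
#'   data frame (label, area_km2, protected_km2, protected_fraction).
#' @export
protected_overlap <- function(hotspots, protected_areas,
                              grid = hotspots$grid) {
  stopifnot(inherits(hotspots, "hotspot_set"),
            inherits(protected_areas, "polygon_set"))
  if (!length(hotspots$hotspots))
    .stopf("no hotspots: protected fraction undefined")
  areas <- cell_areas(grid)
  rows <- lapply(hotspots$hotspots, function(h) {
    lon <- grid$west + (h$cells[, 2L] - 0.5) * grid$res
    lat <- grid$north - (h$cells[, 1L] - 0.5) * grid$res
    prot <- if (length(protected_areas$polygons))
      point_in_polygons(protected_areas, cbind(lon, lat))
    else rep(FALSE, length(lon))
    a <- areas[h$cells]
    data.frame(label = h$label, area_km2 = sum(a),
               protected_km2 = sum(a[prot]),
               protected_fraction = sum(a[prot]) / sum(a))
  })
  per <- do.call(rbind, rows)
  list(outside_fraction = 1 - sum(per$protected_km2) / sum(per$area_km2),
       per_hotspot = per)
}

#' Hotspot polygons as GeoJSON
#'
#' Writes each hotspot as a MultiPolygon of its member-cell rectangles,
#' with label and area properties.
#'
#' @param hotspots a `hotspot_set`.
#' @param path output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_hotspot_geojson <- function(hotspots, path) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  g <- hotspots$grid
  feats <- lapply(hotspots$hotspots, function(h) {
    polys <- lapply(seq_len(nrow(h$cells)), function(i) {
      r <- h$cells[i, 1L]; c <- h$cells[i, 2L]
      w <- g$west + (c - 1) * g$res; e <- w + g$res
      n <- g$north - (r - 1) * g$res; s <- n - g$res
      list(list(c(w, s), c(e, s), c(e, n), c(w, n), c(w, s)))
    })
    list(type = "Feature",
         properties = list(label = h$label, area_km2 = h$area_km2),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
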