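#' Geographic analysis grid
#'
#' A regular lon/lat grid anchored at its north-west corner, row 1
#' northernmost, with a boolean mask marking cells whose centers fall inside
#' the study boundary. Cell centers are at
#' `(west + (c - 0.5) * res, north - (r - 0.5) * res)` for 1-based `(r, c)`.
#'
#' @name grid_spec
NULL

.new_grid_spec <- function(west, north, res, n_rows, n_cols, mask) {
  structure(list(west = west, north = north, res = res,
                 n_rows = n_rows, n_cols = n_cols, mask = mask),
            class = "grid_spec")
}

#' Build the analysis grid over a study boundary
#'
#' The grid covers the boundary bounding box, snapped outward to whole
#' cells (anchored at the west and north edges), and cells are masked in
#' when their center lies inside the boundary polygon.
#'
#' @param boundary a `polygon_set` (or a two-column lon/lat ring matrix).
#' @param resolution cell size in decimal degrees; default 2.5 arc-minutes.
#' @return a `grid_spec`.
#' @examples
#' g <- make_grid(ps_rect(0, 0, 1, 1), resolution = 0.5)
#' g$n_rows; sum(g$mask)
#' @export
make_grid <- function(boundary, resolution = 2.5 / 60) {
  if (is.matrix(boundary)) boundary <- polygon_set(boundary)
  stopifnot(inherits(boundary, "polygon_set"))
  if (!length(boundary$polygons)) .stopf("empty boundary polygon")
  if (!(is.numeric(resolution) && resolution > 0))
    .stopf("resolution must be a positive number of degrees")
  bb <- ps_bbox(boundary)
  n_cols <- as.integer(ceiling((bb["east"] - bb["west"]) / resolution - 1e-9))
  n_rows <- as.integer(ceiling((bb["north"] - bb["south"]) / resolution - 1e-9))
  if (n_cols < 1L || n_rows < 1L) .stopf("degenerate boundary extent")
  g <- .new_grid_spec(unname(bb["west"]), unname(bb["north"]), resolution,
                      n_rows, n_cols,
                      matrix(FALSE, n_rows, n_cols))
  ctr <- cell_centers(g)
  g$mask <- matrix(point_in_polygons(boundary, ctr), n_rows, n_cols)
  g
}

#' Cell-center coordinates of a grid
#'
#' @param grid a `grid_spec`.
#' @return matrix with columns `lon`, `lat`, in column-major cell order
#'   (row index varies fastest, matching R matrix storage).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lon <- grid$west + (seq_len(grid$n_cols) - 0.5) * grid$res
  lat <- grid$north - (seq_len(grid$n_rows) - 0.5) * grid$res
  cbind(lon = rep(lon, each = grid$n_rows),
        lat = rep(lat, times = grid$n_cols))
}

#' Per-cell areas in square kilometres
#'
#' Spherical-cap approximation at the cell-center latitude:
#' `(res * pi/180 * R)^2 * cos(lat)`, with R = 6371.0088 km; areas depend on
#' latitude (row) only.
#'
#' @param grid a `grid_spec`.
#' @return matrix of areas (km^2) with the grid's dimensions.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lat <- grid$north - (seq_len(grid$n_rows) - 0.5) * grid$res
  side <- grid$res * pi / 180 * .EARTH_RADIUS_KM
  matrix(side^2 * cos(lat * pi / 180), grid$n_rows, grid$n_cols)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells at %.6f deg (%.2f arc-min)\n",
              x$n_rows, x$n_cols, x$res, x$res * 60))
  cat(sprintf("  NW corner (%.4f, %.4f); %d of %d cells inside boundary\n",
              x$west, x$north, sum(x$mask), length(x$mask)))
  invisible(x)
}

.same_grid <- function(a, b, tol = 1e-9) {
  abs(a$west - b$west) < tol && abs(a$north - b$north) < tol &&
    abs(a$res - b$res) < tol && a$n_rows == b$n_rows &&
    a$n_cols == b$n_cols
}

#' Genetic landscape surface
#'
#' A single named raster layer on a `grid_spec`: finite values inside the
#' boundary mask, `NA` outside.
#'
#' @param grid a `grid_spec`.
#' @param values numeric matrix of the grid's dimensions (masked-out cells
#'   are forced to `NA`).
#' @param layer_name character scalar.
#' @return object of class `gl_surface`.
#' @export
gl_surface <- function(grid, values, layer_name = "layer") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  values[!grid$mask] <- NA_real_
  if (any(!is.finite(values[grid$mask])))
    .stopf("non-finite surface value inside the boundary mask")
  structure(list(grid = grid, values = values, layer_name = layer_name),
            class = "gl_surface")
}

#' @export
print.gl_surface <- function(x, ...) {
  v <- x$values[x$grid$mask]
  cat(sprintf("gl_surface '%s': %d x %d grid, %d masked-in cells\n",
              x$layer_name, x$grid$n_rows, x$grid$n_cols, length(v)))
  if (length(v))
    cat(sprintf("  range [%.4f, %.4f], mean %.4f\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

#' Write a surface as an ESRI ASCII grid
#'
#' Rows are written north to south; masked-out cells carry the NODATA value.
#'
#' @param surface a `gl_surface`.
#' @param path output path (conventionally `.asc`).
#' @param nodata NODATA marker written to the header.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "gl_surface"))
  g <- surface$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$west),
           sprintf("yllcorner %.10g", g$north - g$n_rows * g$res),
           sprintf("cellsize %.10g", g$res),
           sprintf("NODATA_value %g", nodata))
  v <- surface$values
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row)
    paste(formatC(row, format = "g", digits = 12), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a surface
#'
#' The mask is set to the non-NODATA cells.
#'
#' @param path path to an `.asc` file.
#' @param layer_name name for the layer (default: file stem).
#' @return a `gl_surface`.
#' @export
read_esri_ascii <- function(path,
                            layer_name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) .stopf("raster file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) .stopf("malformed ESRI ASCII header: %s", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = " "),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) .stopf("raster body size mismatch: %s", path)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  west <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  g <- .new_grid_spec(west, yll + nr * hdr$cellsize, hdr$cellsize, nr, nc,
                      !is.na(m))
  gl_surface(g, m, layer_name)
}
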