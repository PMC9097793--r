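#' Inverse-distance-weighted interpolation onto a grid
#'
#' Each masked-in cell takes the weighted mean of the data values with
#' weights `d^(-power)`, `d` the great-circle distance (km) from the cell
#' center to each data point. All points contribute (no search radius).
#' Exactly co-located data points are averaged first; a cell whose center
#' coincides with a data point (< 1e-9 km) reproduces that value exactly.
#'
#' @param points two-column matrix (lon, lat) of data locations.
#' @param values numeric vector of data values, finite.
#' @param grid a `grid_spec`.
#' @param power positive IDW exponent (default 2).
#' @param layer_name name for the output layer.
#' @return a `gl_surface`; values are bounded by `range(values)`.
#' @export
idw_interpolate <- function(points, values, grid, power = 2,
                            layer_name = "idw") {
  stopifnot(inherits(grid, "grid_spec"))
  points <- matrix(as.numeric(points), ncol = 2L)
  if (!nrow(points)) .stopf("IDW requires at least one data point")
  if (length(values) != nrow(points)) .stopf("points/values length mismatch")
  if (any(!is.finite(values))) .stopf("non-finite data value")
  if (!(power > 0)) .stopf("power must be > 0")
  ag <- .average_colocated(points, values)
  points <- ag$points; values <- ag$values
  idx <- which(grid$mask)
  ctr <- cell_centers(grid)[idx, , drop = FALSE]
  phi <- ctr[, 2L] * pi / 180
  cosphi <- cos(phi)
  num <- den <- numeric(length(idx))
  hit <- rep(NA_integer_, length(idx))
  for (i in seq_len(nrow(points))) {
    d <- .haversine_to_point_km(ctr[, 1L], phi, cosphi, points[i, ])
    at <- d < 1e-9
    if (any(at)) hit[at] <- i
    w <- d^(-power)
    w[at] <- 0
    num <- num + w * values[i]
    den <- den + w
  }
  v <- num / den
  v[!is.na(hit)] <- values[hit[!is.na(hit)]]
  if (nrow(points) == 1L) v[] <- values[1L]
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[idx] <- v
  gl_surface(grid, out, layer_name)
}

# average values of exactly co-located points
.average_colocated <- function(points, values) {
  key <- paste(points[, 1L], points[, 2L], sep = "|")
  if (!anyDuplicated(key)) return(list(points = points, values = values))
  f <- factor(key, levels = unique(key))
  list(points = cbind(tapply(points[, 1L], f, `[`, 1L),
                      tapply(points[, 2L], f, `[`, 1L)),
       values = as.numeric(tapply(values, f, mean)))
}

#' Per-species genetic diversity surface
#'
#' IDW interpolation of population haplotype diversities over the study
#' grid; populations at identical coordinates are pre-averaged.
#'
#' @param diversity a diversity table (one species' rows; see
#'   [diversity_table()]).
#' @param grid a `grid_spec`.
#' @param power IDW exponent.
#' @return a `gl_surface` named `hd_<species>`.
#' @export
species_diversity_surface <- function(diversity, grid, power = 2) {
  if (!nrow(diversity)) .stopf("no populations for a diversity surface")
  sp <- unique(diversity$species)
  if (length(sp) > 1L) .stopf("diversity table spans several species")
  idw_interpolate(cbind(diversity$lon, diversity$lat), diversity$hd, grid,
                  power = power, layer_name = paste0("hd_", sp))
}

#' Per-species genetic divergence surface
#'
#' Implements the midpoint construction: each population pair contributes a
#' synthetic point at the arithmetic lon/lat midpoint carrying the pair's
#' Phi-ST, then IDW interpolation over those midpoints. Pair connectivity is
#' all pairs by default, or Delaunay neighbors.
#'
#' @param diversity one species' diversity table (supplies coordinates; row
#'   order must match `fst$pop_ids`).
#' @param fst a `phist_matrix` for the same populations.
#' @param grid a `grid_spec`.
#' @param pair_mode `"all_pairs"` or `"delaunay"`.
#' @param truncate_negative clamp negative Phi-ST to 0 before interpolation
#'   (default `TRUE`).
#' @param power IDW exponent.
#' @return a `gl_surface` named `fst_<species>`.
#' @export
species_divergence_surface <- function(diversity, fst, grid,
                                       pair_mode = c("all_pairs", "delaunay"),
                                       truncate_negative = TRUE, power = 2) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(inherits(fst, "phist_matrix"))
  if (nrow(diversity) < 2L) .stopf("need >= 2 populations for a divergence surface")
  if (!identical(as.character(diversity$pop_id), as.character(fst$pop_ids)))
    .stopf("diversity table and Phi-ST matrix disagree on populations")
  P <- nrow(diversity)
  pairs <- if (pair_mode == "all_pairs") {
    which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  } else {
    delaunay_pairs(cbind(diversity$lon, diversity$lat))
  }
  mid <- cbind((diversity$lon[pairs[, 1L]] + diversity$lon[pairs[, 2L]]) / 2,
               (diversity$lat[pairs[, 1L]] + diversity$lat[pairs[, 2L]]) / 2)
  vals <- fst$values[pairs]
  if (truncate_negative) vals <- pmax(vals, 0)
  idw_interpolate(mid, vals, grid, power = power,
                  layer_name = paste0("fst_", unique(diversity$species)))
}

#' Delaunay neighbor pairs (planar lon/lat)
#'
#' Naive empty-circumcircle construction: a triangle belongs to the
#' triangulation when no other point lies strictly inside its circumcircle;
#' the union of triangle edges gives the neighbor pairs. Duplicate
#' coordinates are collapsed. Intended for the small population counts of
#' this package (tens of points).
#'
#' @param points two-column matrix (lon, lat).
#' @return two-column integer matrix of index pairs (i < j).
#' @export
delaunay_pairs <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2L)
  n <- nrow(points)
  if (n < 2L) .stopf("need >= 2 points")
  if (n == 2L) return(matrix(c(1L, 2L), 1L))
  x <- points[, 1L]; y <- points[, 2L]
  edges <- matrix(integer(), 0L, 2L)
  tri <- utils::combn(n, 3L)
  for (t in seq_len(ncol(tri))) {
    i <- tri[1L, t]; j <- tri[2L, t]; k <- tri[3L, t]
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (length(others) &&
        any((x[others] - ux)^2 + (y[others] - uy)^2 < r2 * (1 - 1e-12)))
      next
    edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  if (!nrow(edges)) {
    # all collinear: chain consecutive points along the line
    o <- order(x, y)
    edges <- cbind(o[-n], o[-1L])
    edges <- t(apply(edges, 1L, sort))
  }
  edges <- unique(edges)
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

#' Combine per-species surfaces into a multi-species landscape
#'
#' Per-cell arithmetic mean across surfaces sharing one grid; a cell is
#' missing only where every input is missing. With `rescale = TRUE` each
#' input is min-max rescaled to `[0, 1]` before averaging.
#'
#' @param surfaces list of `gl_surface` objects on one `grid_spec`.
#' @param layer_name output layer name.
#' @param rescale min-max rescale inputs first (default `FALSE`).
#' @return a `gl_surface`.
#' @export
combine_surfaces <- function(surfaces, layer_name = "combined",
                             rescale = FALSE) {
  if (!length(surfaces)) .stopf("no surfaces to combine")
  g <- surfaces[[1L]]$grid
  for (s in surfaces) {
    stopifnot(inherits(s, "gl_surface"))
    if (!.same_grid(s$grid, g)) .stopf("surfaces on different grids")
  }
  acc <- matrix(0, g$n_rows, g$n_cols)
  cnt <- matrix(0L, g$n_rows, g$n_cols)
  for (s in surfaces) {
    v <- s$values
    if (rescale) {
      rng <- range(v, na.rm = TRUE)
      v <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
    }
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  gl_surface(g, out, layer_name)
}
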