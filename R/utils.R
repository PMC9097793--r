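# internal helpers shared across modules

# mean Earth radius, km (IUGG R1)
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (haversine) distance in kilometres
#'
#' Vectorized over the first argument: distances from each row of `p` to the
#' single point `q`, or elementwise when `q` has the same number of rows.
#'
#' @param p two-column matrix (lon, lat) in decimal degrees, or a length-2
#'   vector.
#' @param q as `p`.
#' @return numeric vector of distances in km on a sphere of radius
#'   6371.0088 km.
#' @keywords internal
#' @noRd
.haversine_km <- function(p, q) {
  p <- matrix(as.numeric(p), ncol = 2L)
  q <- matrix(as.numeric(q), ncol = 2L)
  lam1 <- p[, 1L] * pi / 180; phi1 <- p[, 2L] * pi / 180
  lam2 <- q[, 1L] * pi / 180; phi2 <- q[, 2L] * pi / 180
  a <- sin((phi2 - phi1) / 2)^2 +
    cos(phi1) * cos(phi2) * sin((lam2 - lam1) / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

# haversine distance from many cell centers (precomputed radian lat / cos lat)
# to one point; used in the interpolation inner loop.
.haversine_to_point_km <- function(lon_deg, phi, cosphi, pt) {
  lam <- lon_deg * pi / 180
  lam0 <- pt[1L] * pi / 180
  phi0 <- pt[2L] * pi / 180
  a <- sin((phi0 - phi) / 2)^2 + cosphi * cos(phi0) * sin((lam0 - lam) / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

# all permutations of 1..n as a matrix (n! rows); n is kept tiny (<= 7)
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# A, B, ..., Z, AA, AB, ... labels for ranked hotspots
.letter_labels <- function(k) {
  if (k <= 26L) return(LETTERS[seq_len(k)])
  first <- LETTERS
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(first, extra)[seq_len(k)]
}

# derived sub-seed that stays inside 32-bit integer range
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 7919) %% 2147483647)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
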