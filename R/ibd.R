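#' Geographic distance matrix between populations
#'
#' Great-circle (haversine) distances in km on a sphere of radius
#' 6371.0088 km, or planar lon/lat Euclidean degrees with
#' `method = "planar"`.
#'
#' @param coords two-column matrix (lon, lat); rownames become labels.
#' @param method `"greatcircle"` (default) or `"planar"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
geodesic_distance_matrix <- function(coords,
                                     method = c("greatcircle", "planar")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) .stopf("need >= 2 coordinates")
  if (any(!is.finite(coords)) || any(abs(coords[, 1L]) > 180) ||
      any(abs(coords[, 2L]) > 90))
    .stopf("invalid coordinates")
  n <- nrow(coords)
  D <- matrix(0, n, n, dimnames = list(rownames(coords), rownames(coords)))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    D[i, js] <- D[js, i] <- if (method == "greatcircle") {
      .haversine_km(coords[js, , drop = FALSE], coords[i, ])
    } else {
      sqrt((coords[js, 1L] - coords[i, 1L])^2 +
             (coords[js, 2L] - coords[i, 2L])^2)
    }
  }
  D
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation between the upper triangles of a geographic and a
#' genetic distance matrix, with a one-tailed ("greater") permutation
#' p-value: rows and columns of the genetic matrix are permuted jointly and
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`. For `n <= 7` labels the
#' permutation distribution is enumerated exhaustively and
#' `p = #\{r_perm >= r_obs\} / n!` over all permutations (identity
#' included).
#'
#' @param d_geo,d_gen symmetric matrices with matching dimensions and zero
#'   diagonals (genetic distances may be negative, e.g. raw Phi-ST).
#' @param n_perm number of random permutations (default 999), ignored in
#'   exact mode.
#' @param seed RNG seed for the permutations.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default: exact when `n <= 7`.
#' @param linearize use `d / (1 - d)` of the genetic matrix (Rousset
#'   linearization) before correlating.
#' @return list with `r`, `p`, `n_perm` and `method`
#'   (`"exact"`/`"permutation"`).
#' @export
mantel_test <- function(d_geo, d_gen, n_perm = 999L, seed = 1L,
                        exact = NULL, linearize = FALSE) {
  d_geo <- as.matrix(d_geo); d_gen <- as.matrix(d_gen)
  n <- nrow(d_geo)
  if (!all(dim(d_geo) == c(n, n)) || !all(dim(d_gen) == c(n, n)))
    .stopf("distance matrices must be square and of equal size")
  if (n < 4L) .stopf("Mantel test requires >= 4 populations")
  if (max(abs(d_geo - t(d_geo))) > 1e-12 || max(abs(d_gen - t(d_gen))) > 1e-12)
    .stopf("distance matrices must be symmetric")
  if (linearize) d_gen <- d_gen / (1 - d_gen)
  ut <- upper.tri(d_geo)
  x <- d_geo[ut]
  if (stats::sd(x) == 0 || stats::sd(d_gen[ut]) == 0)
    .stopf("undefined correlation: zero variance in a distance vector")
  r_obs <- stats::cor(x, d_gen[ut])
  if (is.null(exact)) exact <- n <= 7L
  if (exact) {
    perms <- .all_permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      stats::cor(x, d_gen[p, p][ut])
    }, 0)
    p_val <- sum(r_perm >= r_obs - 1e-12) / nrow(perms)
    return(list(r = r_obs, p = p_val, n_perm = nrow(perms),
                method = "exact"))
  }
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(x, d_gen[p, p][ut]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (n_perm + 1), n_perm = n_perm,
       method = "permutation")
}

#' Per-species isolation-by-distance table
#'
#' Runs a Mantel test per species between great-circle geographic distances
#' and raw (untruncated) pairwise Phi-ST.
#'
#' @param diversity multi-species diversity table.
#' @param fst_list named list of `phist_matrix` objects keyed by species.
#' @param n_perm,seed,linearize passed to [mantel_test()].
#' @return data frame: species, n_pops, r, p (species with < 4 populations
#'   or degenerate distance vectors get NA with a note column).
#' @export
ibd_table <- function(diversity, fst_list, n_perm = 999L, seed = 1L,
                      linearize = FALSE) {
  rows <- lapply(names(fst_list), function(sp) {
    fm <- fst_list[[sp]]
    d <- diversity[diversity$species == sp, , drop = FALSE]
    d <- d[match(fm$pop_ids, d$pop_id), , drop = FALSE]
    if (nrow(d) < 4L)
      return(data.frame(species = sp, n_pops = nrow(d), r = NA_real_,
                        p = NA_real_, note = "fewer than 4 populations"))
    res <- tryCatch({
      dg <- geodesic_distance_matrix(cbind(d$lon, d$lat))
      mantel_test(dg, fm$values, n_perm = n_perm,
                  seed = .sub_seed(seed, match(sp, names(fst_list))),
                  linearize = linearize)
    }, error = function(e) NULL)
    if (is.null(res))
      return(data.frame(species = sp, n_pops = nrow(d), r = NA_real_,
                        p = NA_real_, note = "degenerate distances"))
    data.frame(species = sp, n_pops = nrow(d), r = res$r, p = res$p,
               note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
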