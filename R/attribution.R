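#' Sample a raster at arbitrary coordinates (nearest cell)
#'
#' @param raster a `gl_surface` (any grid).
#' @param lon,lat coordinate vectors.
#' @return numeric vector; `NA` where a point falls off the raster.
#' @export
sample_raster <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "gl_surface"))
  g <- raster$grid
  col <- floor((lon - g$west) / g$res) + 1L
  row <- floor((g$north - lat) / g$res) + 1L
  ok <- row >= 1L & row <= g$n_rows & col >= 1L & col <= g$n_cols
  out <- rep(NA_real_, length(lon))
  out[ok] <- raster$values[cbind(row[ok], col[ok])]
  out
}

#' Assemble the per-cell explanatory variable table
#'
#' One row per masked-in cell of the response surface, with the response
#' (`hd`) and every explanatory raster sampled at the cell center
#' (nearest-neighbor when raster grids differ). Rows with any missing
#' variable are dropped and counted in attribute `n_dropped`. Variable
#' categories are kept in attribute `categories` (named character vector).
#'
#' @param rasters list of entries `list(name=, category=, raster=)`; the
#'   raster is a `gl_surface`; category one of `"climatic"`,
#'   `"topographic"`, `"anthropogenic"`.
#' @param surface the combined diversity `gl_surface` (the response).
#' @return data frame with columns `cell, row, col, lon, lat, hd, <vars>`;
#'   attributes `categories`, `n_dropped`.
#' @export
extract_variable_table <- function(rasters, surface) {
  stopifnot(inherits(surface, "gl_surface"))
  g <- surface$grid
  idx <- which(g$mask)
  ctr <- cell_centers(g)[idx, , drop = FALSE]
  tab <- data.frame(cell = idx,
                    row = ((idx - 1L) %% g$n_rows) + 1L,
                    col = ((idx - 1L) %/% g$n_rows) + 1L,
                    lon = ctr[, 1L], lat = ctr[, 2L],
                    hd = surface$values[idx])
  cats <- character()
  for (r in rasters) {
    if (!all(c("name", "category", "raster") %in% names(r)))
      .stopf("each raster entry needs name, category and raster")
    if (!r$category %in% c("climatic", "topographic", "anthropogenic"))
      .stopf("unknown category '%s' for variable '%s'", r$category, r$name)
    v <- sample_raster(r$raster, ctr[, 1L], ctr[, 2L])
    if (all(is.na(v)))
      .stopf("raster '%s' has no overlap with the analysis grid", r$name)
    tab[[r$name]] <- v
    cats[r$name] <- r$category
  }
  keep <- stats::complete.cases(tab)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "categories") <- cats
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Within-category collinearity filter
#'
#' Iteratively removes one member of the most correlated within-category
#' pair until no pair exceeds the threshold: at each step the pair with the
#' highest |r| is found and the member with the larger mean |r| against all
#' other remaining variables is dropped (ties drop the lexicographically
#' later name). Categories are filtered independently.
#'
#' @param table a variable table from [extract_variable_table()].
#' @param threshold correlation cut (default 0.7 on |r|).
#' @return character vector of retained variable names; attribute
#'   `dropped` lists removals.
#' @export
collinearity_filter <- function(table, threshold = 0.7) {
  cats <- attr(table, "categories")
  if (is.null(cats)) .stopf("table lacks a categories attribute")
  retained <- character(); dropped <- character()
  for (cat in unique(cats)) {
    vars <- names(cats)[cats == cat]
    while (length(vars) > 1L) {
      C <- abs(stats::cor(table[vars]))
      diag(C) <- 0
      if (max(C) <= threshold) break
      pair <- which(C == max(C), arr.ind = TRUE)[1L, ]
      a <- vars[pair[1L]]; b <- vars[pair[2L]]
      mean_r <- function(v) mean(C[v, setdiff(vars, v)])
      drop <- if (mean_r(a) > mean_r(b)) a
              else if (mean_r(b) > mean_r(a)) b
              else sort(c(a, b))[2L]
      vars <- setdiff(vars, drop)
      dropped <- c(dropped, drop)
    }
    retained <- c(retained, vars)
  }
  # preserve original column order
  retained <- names(cats)[names(cats) %in% retained]
  attr(retained, "dropped") <- dropped
  retained
}

#' Select the most important variables of a category
#'
#' Ranks a category's variables by random-forest permutation importance
#' (mean decrease in accuracy/MSE) for predicting the diversity response
#' and returns the top `k`. A category with exactly `k` variables is
#' returned as-is without fitting. The forest is grown on a seeded
#' subsample of at most `max_cells` rows.
#'
#' @param table a variable table (with `categories` attribute).
#' @param category category to screen.
#' @param k number of variables to keep (default 2).
#' @param seed RNG seed (selection is deterministic given the seed).
#' @param n_rep permutation repeats per tree (`nPerm`, default 10).
#' @param n_tree forest size (default 500).
#' @param max_cells subsample cap (default 10000).
#' @param flavor `"permutation"` (default) or `"impurity"` importance.
#' @return character vector of the top-k variable names (importance order).
#' @export
importance_select <- function(table, category, k = 2L, seed = 1L,
                              n_rep = 10L, n_tree = 500L,
                              max_cells = 10000L,
                              flavor = c("permutation", "impurity")) {
  flavor <- match.arg(flavor)
  cats <- attr(table, "categories")
  vars <- names(cats)[cats == category]
  if (length(vars) < k)
    .stopf("category '%s' has %d variable(s), fewer than k = %d",
           category, length(vars), k)
  if (length(vars) == k) return(vars)
  set.seed(seed)
  rows <- if (nrow(table) > max_cells)
    sort(sample.int(nrow(table), max_cells)) else seq_len(nrow(table))
  x <- table[rows, vars, drop = FALSE]
  y <- table$hd[rows]
  fit <- randomForest::randomForest(x, y, ntree = n_tree,
                                    importance = flavor == "permutation",
                                    nPerm = n_rep)
  imp <- randomForest::importance(fit,
                                  type = if (flavor == "permutation") 1L else 2L,
                                  scale = FALSE)
  ranked <- vars[order(-imp[vars, 1L], vars)]
  ranked[seq_len(k)]
}

#' Univariate GAM of diversity against one variable
#'
#' Penalized thin-plate spline with automatic smoothness selection
#' (restricted-likelihood by default), as a one-term generalized additive
#' model `y ~ s(x, k = basis_dim)`.
#'
#' @param x predictor vector.
#' @param y response vector.
#' @param basis_dim spline basis dimension (default 10).
#' @param method mgcv smoothness-selection method (`"REML"` default,
#'   `"GCV.Cp"` for GCV).
#' @return object of class `gam_fit`: list with the mgcv `model`, `r2_adj`,
#'   `p_value` and `edf` of the smooth, `trend` (sign of the overall linear
#'   drift of the fitted smooth), and `smooth_fun(x)` to evaluate the fit.
#' @export
fit_gam <- function(x, y, basis_dim = 10L, method = c("REML", "GCV.Cp")) {
  method <- match.arg(method)
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) .stopf("non-finite values")
  if (length(x) <= basis_dim) .stopf("need n > basis_dim observations")
  if (stats::sd(x) == 0) .stopf("constant predictor: rank-deficient smooth")
  # the basis cannot exceed the number of distinct covariate values
  k_eff <- min(basis_dim, length(unique(x)))
  if (k_eff < 3L) .stopf("too few distinct predictor values for a smooth")
  dat <- data.frame(x = x, y = y)
  model <- mgcv::gam(y ~ s(x, k = k_eff), data = dat, method = method)
  sm <- summary(model)
  xs <- seq(stats::quantile(x, 0.05), stats::quantile(x, 0.95), length.out = 101)
  fit_line <- as.numeric(stats::predict(model, data.frame(x = xs)))
  trend <- sign(stats::coef(stats::lm(fit_line ~ xs))[2L])
  structure(list(model = model,
                 r2_adj = unname(sm$r.sq),
                 p_value = unname(sm$s.table[1L, "p-value"]),
                 edf = unname(sm$s.table[1L, "edf"]),
                 trend = unname(trend),
                 smooth_fun = function(newx)
                   as.numeric(stats::predict(model, data.frame(x = newx)))),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("gam_fit: adj. R2 = %.3f, edf = %.2f, p = %.3g, trend %s\n",
              x$r2_adj, x$edf, x$p_value,
              if (is.na(x$trend)) "flat" else if (x$trend > 0) "increasing"
              else "decreasing"))
  invisible(x)
}

#' Ezekiel's adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`.
#'
#' @param r2 coefficient of determination in `[0, 1]`.
#' @param n number of observations.
#' @param p number of predictors.
#' @return adjusted R-squared (may be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) .stopf("adjusted R2 undefined: n <= p + 1")
  if (r2 < 0 || r2 > 1) .stopf("R2 outside [0, 1]")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# plain OLS R2 of y on a set of columns (with intercept)
.ols_r2 <- function(y, X) {
  if (!ncol(X)) return(0)
  Xm <- cbind(1, as.matrix(X))
  qr_x <- qr(Xm)
  if (qr_x$rank < ncol(Xm)) {
    bad <- colnames(Xm)[qr_x$pivot[(qr_x$rank + 1L):ncol(Xm)]]
    .stopf("rank-deficient design; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  res <- qr.resid(qr_x, y)
  1 - sum(res^2) / sum((y - mean(y))^2)
}

#' Variation partitioning among three explanatory sets
#'
#' Decomposes the adjusted R-squared of a linear model of the diversity
#' response on climatic (C), topographic (T) and anthropogenic (A)
#' predictor sets into seven unique/shared fractions. With a univariate
#' response, redundancy analysis reduces to multiple linear regression, so
#' the seven models C, T, A, CT, CA, TA, CTA are fitted by OLS, each
#' R-squared is Ezekiel-adjusted, and the fractions are solved from the
#' inclusion-exclusion linear system (so they sum exactly to
#' adj-R2(CTA)). Fractions may be slightly negative, a known artifact of
#' adjusted R-squared.
#'
#' @param table a variable table (response column `hd`).
#' @param sets named list `list(C = ..., T = ..., A = ...)` of disjoint
#'   variable-name vectors (all present in `table`).
#' @return object of class `varpart_result`: list with `r2_adj` (the 7
#'   model values), `fractions` (named: unique_C, unique_T, unique_A,
#'   shared_CT, shared_TA, shared_CA, shared_CTA), `residual`, `n`.
#' @export
variation_partition <- function(table, sets) {
  if (!all(c("C", "T", "A") %in% names(sets)))
    .stopf("sets must be a named list with C, T and A")
  all_vars <- unlist(sets)
  if (anyDuplicated(all_vars)) .stopf("explanatory sets must be disjoint")
  miss <- setdiff(all_vars, names(table))
  if (length(miss)) .stopf("variables absent from table: %s",
                           paste(miss, collapse = ", "))
  y <- table$hd
  n <- length(y)
  models <- list(C = sets$C, T = sets$T, A = sets$A,
                 CT = c(sets$C, sets$T), CA = c(sets$C, sets$A),
                 TA = c(sets$T, sets$A), CTA = all_vars)
  r2a <- vapply(models, function(v) {
    adjusted_r2(.ols_r2(y, table[v]), n, length(v))
  }, 0)
  # fractions a..g: unique C, unique T, unique A, CT-only, TA-only,
  # CA-only, CTA; rows map fractions to the seven model adj-R2 values
  M <- rbind(
    C   = c(1, 0, 0, 1, 0, 1, 1),
    T   = c(0, 1, 0, 1, 1, 0, 1),
    A   = c(0, 0, 1, 0, 1, 1, 1),
    CT  = c(1, 1, 0, 1, 1, 1, 1),
    CA  = c(1, 0, 1, 1, 1, 1, 1),
    TA  = c(0, 1, 1, 1, 1, 1, 1),
    CTA = c(1, 1, 1, 1, 1, 1, 1))
  fr <- solve(M, r2a[rownames(M)])
  fractions <- stats::setNames(as.numeric(fr),
                               c("unique_C", "unique_T", "unique_A",
                                 "shared_CT", "shared_TA", "shared_CA",
                                 "shared_CTA"))
  structure(list(r2_adj = r2a, fractions = fractions,
                 residual = 1 - r2a[["CTA"]], n = n, sets = sets),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("variation partitioning (n = %d): adj. R2 full model = %.3f\n",
              x$n, x$r2_adj[["CTA"]]))
  for (nm in names(x$fractions))
    cat(sprintf("  %-11s %8.4f\n", nm, x$fractions[[nm]]))
  cat(sprintf("  %-11s %8.4f\n", "residual", x$residual))
  invisible(x)
}
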