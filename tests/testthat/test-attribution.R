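# variable extraction, screening, GAMs and variation partitioning

grid4 <- function(res = 0.25) make_grid(ps_rect(0, 0, 2, 2), resolution = res)

const_raster <- function(g, value, name = "v") {
  full <- g; full$mask <- matrix(TRUE, g$n_rows, g$n_cols)
  gl_surface(full, matrix(value, g$n_rows, g$n_cols), name)
}

test_that("variable extraction samples cell centers and drops incomplete rows", {
  g <- grid4()
  resp <- gl_surface(g, matrix(runif(length(g$mask)), g$n_rows, g$n_cols))
  full <- g; full$mask <- matrix(TRUE, g$n_rows, g$n_cols)
  ctr <- cell_centers(full)
  rasters <- list(
    list(name = "c7", category = "climatic", raster = const_raster(g, 7)),
    list(name = "lat", category = "topographic",
         raster = gl_surface(full, matrix(ctr[, 2], g$n_rows, g$n_cols))),
    list(name = "long", category = "topographic",
         raster = gl_surface(full, matrix(ctr[, 1], g$n_rows, g$n_cols))))
  tab <- extract_variable_table(rasters, resp)
  expect_equal(nrow(tab), sum(g$mask))
  expect_true(all(tab$c7 == 7))
  expect_equal(tab$lat, tab$lat)
  expect_equal(tab[["lat"]], tab$lat)
  expect_equal(tab$lat, cell_centers(g)[which(g$mask), 2])
  expect_equal(tab$long, cell_centers(g)[which(g$mask), 1])
  expect_equal(attr(tab, "n_dropped"), 0L)

  # a raster covering only part of the grid drops the uncovered rows
  gsmall <- make_grid(ps_rect(0, 0, 1, 2), resolution = 0.25)
  partial <- const_raster(gsmall, 1, "part")
  tab2 <- extract_variable_table(c(rasters, list(
    list(name = "part", category = "anthropogenic", raster = partial))), resp)
  n_off <- sum(cell_centers(g)[which(g$mask), 1] > 1)
  expect_equal(attr(tab2, "n_dropped"), n_off)
  expect_equal(nrow(tab2), sum(g$mask) - n_off)

  # raster with no overlap at all is an error
  far <- const_raster(make_grid(ps_rect(50, 50, 51, 51), 0.25), 1)
  expect_error(extract_variable_table(list(
    list(name = "far", category = "climatic", raster = far)), resp),
    "no overlap")
})

test_that("collinearity filter removes exactly the high-correlation redundancy", {
  set.seed(61)
  n <- 500L
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- x1 + rnorm(n, 0, 0.1)
  x4 <- 0.5 * x1 + 0.5 * x2 + rnorm(n, 0, 1)
  tab <- data.frame(hd = rnorm(n), a = x1, b = x2, c = x3, d = x4)
  attr(tab, "categories") <- c(a = "climatic", b = "climatic",
                               c = "climatic", d = "climatic")
  kept <- collinearity_filter(tab, 0.7)
  # brute force: no surviving pair above the threshold
  C <- abs(cor(tab[kept])); diag(C) <- 0
  expect_lte(max(C), 0.7)
  expect_true(all(c("b", "d") %in% kept))
  expect_equal(sort(union(kept, attr(kept, "dropped"))),
               c("a", "b", "c", "d"))
  # idempotence
  tab2 <- tab[c("hd", kept)]
  attr(tab2, "categories") <- attr(tab, "categories")[kept]
  expect_equal(as.character(collinearity_filter(tab2, 0.7)),
               as.character(kept))

  # duplicated column: exactly one of the pair is dropped
  dup <- data.frame(hd = rnorm(n), u = x1, v = x1)
  attr(dup, "categories") <- c(u = "topographic", v = "topographic")
  kept_dup <- collinearity_filter(dup, 0.7)
  expect_equal(length(kept_dup), 1L)
  # no pair exceeding the threshold: identity
  ind <- data.frame(hd = rnorm(n), a = x1, b = x2)
  attr(ind, "categories") <- c(a = "climatic", b = "climatic")
  expect_equal(as.character(collinearity_filter(ind, 0.7)), c("a", "b"))
  # the filter works within, never across, categories
  cross <- data.frame(hd = rnorm(n), a = x1, b = x3)
  attr(cross, "categories") <- c(a = "climatic", b = "topographic")
  expect_equal(as.character(collinearity_filter(cross, 0.7)), c("a", "b"))
})

test_that("importance screening finds a planted signal and is seed-deterministic", {
  make_tab <- function(seed) {
    set.seed(seed)
    n <- 400L
    x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
    tab <- data.frame(hd = sin(2 * pi * x1) + rnorm(n, 0, 0.1),
                      x1 = x1, x2 = x2, x3 = x3)
    attr(tab, "categories") <- c(x1 = "climatic", x2 = "climatic",
                                 x3 = "climatic")
    tab
  }
  hits <- 0L
  for (s in 1:10) {
    sel <- importance_select(make_tab(s), "climatic", k = 1L, seed = s,
                             n_tree = 200L)
    if (sel == "x1") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # pass-through when the category has exactly k variables
  tab <- make_tab(1)
  attr(tab, "categories") <- c(x1 = "climatic", x2 = "climatic",
                               x3 = "anthropogenic")
  expect_equal(importance_select(tab, "climatic", k = 2L, seed = 1),
               c("x1", "x2"))
  expect_error(importance_select(tab, "anthropogenic", k = 2L, seed = 1),
               "fewer than k")
  # bit-identical output under one seed
  s1 <- importance_select(make_tab(3), "climatic", k = 2L, seed = 99,
                          n_tree = 100L)
  s2 <- importance_select(make_tab(3), "climatic", k = 2L, seed = 99,
                          n_tree = 100L)
  expect_identical(s1, s2)
})

test_that("GAM fits recover planted smooth and linear signals", {
  set.seed(71)
  # null: constant response
  x <- runif(500)
  g0 <- fit_gam(x, rep(0.5, 500) + rnorm(500, 0, 1e-8))
  expect_lt(abs(g0$r2_adj), 0.02)
  # smooth signal
  y <- sin(2 * pi * x) + rnorm(500, 0, 0.05)
  g1 <- fit_gam(x, y)
  expect_gt(g1$r2_adj, 0.9)
  expect_lt(g1$p_value, 1e-6)
  fitted_mid <- g1$smooth_fun(c(0.25, 0.75))
  expect_equal(fitted_mid, c(1, -1), tolerance = 0.1)
  # linear signal: monotone fit over the central 90% of x
  x2 <- runif(1000); y2 <- 2 * x2 + rnorm(1000)
  g2 <- fit_gam(x2, y2)
  xs <- seq(quantile(x2, 0.05), quantile(x2, 0.95), length.out = 50)
  expect_true(all(diff(g2$smooth_fun(xs)) > 0))
  expect_equal(g2$trend, 1)
  expect_error(fit_gam(rep(1, 100), rnorm(100)), "constant")
  expect_error(fit_gam(1:5, 1:5), "basis_dim")
})

test_that("Ezekiel adjustment follows its closed form", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_equal(adjusted_r2(0, 100, 2), -2 / 97)
  expect_equal(adjusted_r2(0.42, 100, 0), 0.42)
  expect_error(adjusted_r2(0.5, 4, 3), "n <= p")
})

test_that("variation partitioning matches a normal-equations oracle and closes", {
  set.seed(81)
  n <- 800L
  zT <- rnorm(n); zS <- rnorm(n); zC <- rnorm(n); zA <- rnorm(n)
  tab <- data.frame(hd = zT + zS + rnorm(n),
                    c1 = zS + 0.3 * rnorm(n), c2 = zC,
                    t1 = zT + 0.2 * zS, t2 = rnorm(n),
                    a1 = zA)
  sets <- list(C = c("c1", "c2"), T = c("t1", "t2"), A = "a1")
  res <- variation_partition(tab, sets)
  # oracle: R2 via explicit normal equations for each of the 7 models
  r2_ne <- function(vars) {
    X <- cbind(1, as.matrix(tab[vars]))
    beta <- solve(t(X) %*% X, t(X) %*% tab$hd)
    fit <- X %*% beta
    1 - sum((tab$hd - fit)^2) / sum((tab$hd - mean(tab$hd))^2)
  }
  mods <- list(C = sets$C, T = sets$T, A = sets$A,
               CT = c(sets$C, sets$T), CA = c(sets$C, sets$A),
               TA = c(sets$T, sets$A), CTA = unlist(sets))
  a2 <- sapply(mods, function(v) adjusted_r2(r2_ne(v), n, length(v)))
  # hand inclusion-exclusion for the seven fractions
  want <- c(unique_C = a2[["CTA"]] - a2[["TA"]],
            unique_T = a2[["CTA"]] - a2[["CA"]],
            unique_A = a2[["CTA"]] - a2[["CT"]],
            shared_CT = a2[["CA"]] + a2[["TA"]] - a2[["A"]] - a2[["CTA"]],
            shared_TA = a2[["CA"]] + a2[["CT"]] - a2[["C"]] - a2[["CTA"]],
            shared_CA = a2[["CT"]] + a2[["TA"]] - a2[["T"]] - a2[["CTA"]],
            shared_CTA = a2[["C"]] + a2[["T"]] + a2[["A"]] -
              a2[["CT"]] - a2[["CA"]] - a2[["TA"]] + a2[["CTA"]])
  expect_equal(res$fractions, want, tolerance = 1e-10)
  expect_equal(sum(res$fractions), res$r2_adj[["CTA"]], tolerance = 1e-10)
  expect_equal(res$residual, 1 - res$r2_adj[["CTA"]], tolerance = 1e-12)
})

test_that("variation partitioning agrees with an independent varpart implementation", {
  skip_if_not_installed("vegan")
  set.seed(82)
  n <- 500L
  tab <- data.frame(hd = rnorm(n), c1 = rnorm(n), c2 = rnorm(n),
                    t1 = rnorm(n), a1 = rnorm(n))
  tab$hd <- tab$c1 + 0.5 * tab$t1 + rnorm(n)
  res <- variation_partition(tab, list(C = c("c1", "c2"), T = "t1", A = "a1"))
  vp <- vegan::varpart(tab$hd, tab[c("c1", "c2")], tab["t1"], tab["a1"])
  ind <- vp$part$indfract$Adj.R.square
  # vegan order: [a]=X1, [b]=X2, [c]=X3, [d]=X1&X2, [e]=X2&X3, [f]=X1&X3, [g]=all
  expect_equal(unname(res$fractions[c("unique_C", "unique_T", "unique_A",
                                      "shared_CT", "shared_TA", "shared_CA",
                                      "shared_CTA")]),
               ind[1:7], tolerance = 1e-8)
})

test_that("degenerate partitions behave: single-source and pure-noise limits", {
  set.seed(83)
  n <- 2000L
  tab <- data.frame(t1 = rnorm(n), t2 = rnorm(n), c1 = rnorm(n),
                    a1 = rnorm(n))
  tab$hd <- 2 * tab$t1 - tab$t2  # noiseless topographic response
  res <- variation_partition(tab, list(C = "c1", T = c("t1", "t2"), A = "a1"))
  expect_gt(res$fractions[["unique_T"]], 0.98)
  others <- res$fractions[setdiff(names(res$fractions), "unique_T")]
  expect_true(all(abs(others) < 0.02))
  # pure noise: all fractions near zero
  tab$hd <- rnorm(n)
  res0 <- variation_partition(tab, list(C = "c1", T = c("t1", "t2"), A = "a1"))
  expect_true(all(abs(res0$fractions) < 0.02))
  # collinear design is named in the error
  tab$t3 <- tab$t1
  expect_error(variation_partition(tab, list(C = "c1", T = c("t1", "t3"),
                                             A = "a1")), "t3")
})

test_that("orthogonal predictor sets recover their variance shares", {
  set.seed(84)
  rel_err <- replicate(20, {
    n <- 5000L
    xc <- rnorm(n); xt <- rnorm(n); xa <- rnorm(n)
    y <- 1.0 * xc + 1.5 * xt + 0.5 * xa + rnorm(n, 0, 1)
    tab <- data.frame(hd = y, c1 = xc, t1 = xt, a1 = xa)
    res <- variation_partition(tab, list(C = "c1", T = "t1", A = "a1"))
    V <- 1 + 1.5^2 + 0.5^2 + 1
    got <- res$fractions[c("unique_C", "unique_T", "unique_A")]
    want <- c(1, 2.25, 0.25) / V
    max(abs(got - want) / want)
  })
  expect_lt(mean(rel_err), 0.10)
})
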