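#' Synthetic-study configuration
#'
#' Defines the conditions a generated study emulates: a regional bounding
#' box, per-species population sampling, a planted south-to-north haplotype
#' diversity gradient (implemented through the concentration of the
#' Dirichlet prior on haplotype frequencies), category-tagged environmental
#' rasters with a known climate-latitude coupling, and protected areas of
#' known coverage.
#'
#' @param bbox named vector (west, east, south, north); defaults to the
#'   Longitudinal Range Gorge Region printed bounds.
#' @param n_species number of species (default 15).
#' @param pops_range min/max populations per species (default 8-30).
#' @param n_range min/max sampled individuals per population (default
#'   5-20; the minimum must be >= 5 unless `contaminate`).
#' @param n_haplotypes haplotype pool size per species (default 12).
#' @param seq_length alignment length in bp (default 600).
#' @param mutations_per_hap substitutions from the root per haplotype
#'   (default 3).
#' @param gradient_direction `"north"`, `"south"`, `"east"`, `"west"` or
#'   `"none"`.
#' @param gradient_strength log-scale range of the Dirichlet concentration
#'   across the region (default 4; 0 plants no gradient).
#' @param base_concentration Dirichlet concentration at the region center
#'   (default 0.2; small values make near-monomorphic populations common,
#'   as in real cpDNA data).
#' @param climate_slope latitude loading of the climatic rasters
#'   (default 0.6), inducing a known climate-topography overlap.
#' @param raster_noise_sd loading of each raster's own orthonormal noise
#'   field (default 0.8).
#' @param pa_coverage protected-area coverage fraction in `[0, 1]`
#'   (default 0.3).
#' @param contaminate also generate undersampled populations (N < 5) to
#'   exercise the sample-size filter (default `FALSE`).
#' @param n_small undersampled populations per species when contaminating.
#' @param seed master seed; identical seeds give byte-identical bundles.
#' @return object of class `study_config`.
#' @export
study_config <- function(bbox = c(west = 95.79, east = 106.12,
                                  south = 21.15, north = 30.60),
                         n_species = 15L, pops_range = c(8L, 30L),
                         n_range = c(5L, 20L), n_haplotypes = 12L,
                         seq_length = 600L, mutations_per_hap = 3L,
                         gradient_direction = "north",
                         gradient_strength = 4,
                         base_concentration = 0.2,
                         climate_slope = 0.6, raster_noise_sd = 0.8,
                         pa_coverage = 0.3, contaminate = FALSE,
                         n_small = 3L, seed = 42L) {
  stopifnot(all(c("west", "east", "south", "north") %in% names(bbox)),
            bbox["east"] > bbox["west"], bbox["north"] > bbox["south"],
            n_species >= 1L, pops_range[1L] >= 1L,
            pops_range[2L] >= pops_range[1L],
            n_range[1L] >= 1L, n_range[2L] >= n_range[1L],
            n_haplotypes >= 2L, seq_length >= 1L,
            gradient_strength >= 0, base_concentration > 0,
            pa_coverage >= 0, pa_coverage <= 1)
  if (!gradient_direction %in% c("north", "south", "east", "west", "none"))
    .stopf("unknown gradient direction '%s'", gradient_direction)
  if (n_haplotypes < 2L && gradient_strength > 0)
    .stopf("a diversity gradient needs a haplotype pool of >= 2")
  structure(list(bbox = bbox, n_species = as.integer(n_species),
                 pops_range = as.integer(pops_range),
                 n_range = as.integer(n_range),
                 n_haplotypes = as.integer(n_haplotypes),
                 seq_length = as.integer(seq_length),
                 mutations_per_hap = as.integer(mutations_per_hap),
                 gradient_direction = gradient_direction,
                 gradient_strength = gradient_strength,
                 base_concentration = base_concentration,
                 climate_slope = climate_slope,
                 raster_noise_sd = raster_noise_sd,
                 pa_coverage = pa_coverage,
                 contaminate = isTRUE(contaminate),
                 n_small = as.integer(n_small),
                 seed = as.integer(seed)),
            class = "study_config")
}

# position of (lon, lat) along the gradient direction, in [0, 1]
.gradient_position <- function(config, lon, lat) {
  bb <- config$bbox
  switch(config$gradient_direction,
         north = (lat - bb[["south"]]) / (bb[["north"]] - bb[["south"]]),
         south = (bb[["north"]] - lat) / (bb[["north"]] - bb[["south"]]),
         east = (lon - bb[["west"]]) / (bb[["east"]] - bb[["west"]]),
         west = (bb[["east"]] - lon) / (bb[["east"]] - bb[["west"]]),
         none = rep(0.5, length(lat)))
}

#' Simulate one species' haplotype dataset
#'
#' Builds a haplotype pool by seeded random substitutions from a random
#' root sequence, scatters populations uniformly over the region, and draws
#' per-population haplotype counts multinomially from Dirichlet frequency
#' vectors whose concentration increases along the gradient direction, so
#' expected haplotype diversity rises along the gradient. The analytic
#' expectation `E[1 - sum p_i^2] = (K - 1) a / (K a + 1)` for a symmetric
#' Dirichlet(a) with K haplotypes is recorded as ground truth.
#'
#' @param config a `study_config`.
#' @param species_index 1-based species number (drives the sub-seed).
#' @return a `species_dataset`; attribute `ground_truth` is a data frame
#'   with per-population gradient position, Dirichlet concentration and
#'   expected diversity, plus attribute `n_small` undersampled populations
#'   when contaminating.
#' @export
simulate_species_dataset <- function(config, species_index) {
  stopifnot(inherits(config, "study_config"))
  set.seed(.sub_seed(config$seed, species_index))
  K <- config$n_haplotypes; L <- config$seq_length
  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  haps <- vapply(seq_len(K), function(k) {
    s <- root
    if (k > 1L) {
      pos <- sample.int(L, min(config$mutations_per_hap, L))
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    }
    paste(s, collapse = "")
  }, "")
  names(haps) <- sprintf("h%02d", seq_len(K))
  n_pops <- if (config$pops_range[1L] == config$pops_range[2L])
    config$pops_range[1L]
  else sample(config$pops_range[1L]:config$pops_range[2L], 1L)
  bb <- config$bbox
  lon <- round(stats::runif(n_pops, bb[["west"]], bb[["east"]]), 6)
  lat <- round(stats::runif(n_pops, bb[["south"]], bb[["north"]]), 6)
  s_pos <- .gradient_position(config, lon, lat)
  alpha <- config$base_concentration *
    exp(config$gradient_strength * (s_pos - 0.5))
  pops <- vector("list", n_pops)
  truth <- data.frame(pop_id = sprintf("p%02d", seq_len(n_pops)),
                      lon = lon, lat = lat, position = s_pos,
                      alpha = alpha,
                      expected_hd = (K - 1) * alpha / (K * alpha + 1))
  for (i in seq_len(n_pops)) {
    N <- if (config$n_range[1L] == config$n_range[2L]) config$n_range[1L]
         else sample(config$n_range[1L]:config$n_range[2L], 1L)
    gam <- stats::rgamma(K, shape = alpha[i])
    while (sum(gam) == 0) gam <- stats::rgamma(K, shape = alpha[i])
    cnt <- as.integer(stats::rmultinom(1L, N, gam / sum(gam)))
    names(cnt) <- names(haps)
    pops[[i]] <- list(pop_id = truth$pop_id[i], lon = lon[i], lat = lat[i],
                      counts = cnt[cnt > 0])
  }
  n_small <- 0L
  if (config$contaminate && config$n_small > 0L) {
    for (j in seq_len(config$n_small)) {
      slon <- round(stats::runif(1L, bb[["west"]], bb[["east"]]), 6)
      slat <- round(stats::runif(1L, bb[["south"]], bb[["north"]]), 6)
      cnt <- structure(as.integer(sample(1:4, 1L)), names = names(haps)[1L])
      pops[[length(pops) + 1L]] <-
        list(pop_id = sprintf("small%02d", j), lon = slon, lat = slat,
             counts = cnt)
      n_small <- n_small + 1L
    }
  }
  ds <- species_dataset(sprintf("species_%02d", species_index), haps, pops)
  attr(ds, "ground_truth") <- truth
  attr(ds, "n_small") <- n_small
  ds
}

# seeded smooth field: sum of random Gaussian bumps over the grid centers
.smooth_field <- function(grid, n_bumps = 6L, amplitude = 1) {
  bb <- c(grid$west, grid$west + grid$n_cols * grid$res,
          grid$north - grid$n_rows * grid$res, grid$north)
  ctr <- cell_centers(grid)
  f <- numeric(nrow(ctr))
  for (b in seq_len(n_bumps)) {
    mx <- stats::runif(1L, bb[1L], bb[2L])
    my <- stats::runif(1L, bb[3L], bb[4L])
    sg <- stats::runif(1L, 0.15, 0.4) * max(bb[2L] - bb[1L], bb[4L] - bb[3L])
    a <- stats::rnorm(1L, 0, amplitude)
    f <- f + a * exp(-((ctr[, 1L] - mx)^2 + (ctr[, 2L] - my)^2) / (2 * sg^2))
  }
  matrix(f, grid$n_rows, grid$n_cols)
}

#' Simulate the environmental raster stack
#'
#' Topographic variables are the coordinate fields (`lat`, `long`) plus
#' smooth seeded terrain fields (`elev`, `tri`); climatic variables (`cld`,
#' `wet`, `tmp`, `pre`) load on latitude (with the sign and weight set by
#' `climate_slope`), which plants a known climate-topography overlap;
#' anthropogenic variables (`ahf`, `hfp`) are independent noise fields with
#' no planted link to diversity. Noise fields are smooth Gaussian-bump
#' mixtures orthonormalized against the coordinate fields and each other,
#' so pairwise correlations are controlled by construction: `tmp` is built
#' to correlate at about 0.9 with `cld` (exercising the collinearity
#' filter) while every other within-category pair stays clearly below 0.7.
#'
#' @param config a `study_config`; `climate_slope` is the latitude loading
#'   of `cld`/`wet` (default 0.6) and `raster_noise_sd` the loading of each
#'   variable's own orthonormal noise field (default 0.8; 0 makes `cld`,
#'   `wet`, `tmp` exact affine functions of latitude).
#' @param grid a `grid_spec`.
#' @return list of entries `list(name, category, raster)` (the manifest
#'   form consumed by [extract_variable_table()]).
#' @export
simulate_environment_rasters <- function(config, grid) {
  stopifnot(inherits(config, "study_config"), inherits(grid, "grid_spec"))
  set.seed(.sub_seed(config$seed, 101L))
  full <- grid
  full$mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  ctr <- cell_centers(full)
  std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  latn <- std(ctr[, 2L]); lonn <- std(ctr[, 1L])
  raw <- vapply(1:8, function(i) as.vector(.smooth_field(full)), latn)
  # orthonormalize the noise fields against the intercept, lat/lon and one
  # another, so planted correlations are exact by construction
  basis <- cbind(1, latn, lonn, raw)
  E <- if (length(latn) >= 11L && qr(basis)$rank == 11L) {
    apply(qr.Q(qr(basis))[, 4:11, drop = FALSE], 2L, std)
  } else {
    apply(raw, 2L, std)
  }
  if (any(!is.finite(E))) E[!is.finite(E)] <- 0
  a <- config$climate_slope; b <- config$raster_noise_sd
  cld <- -(a * latn + b * E[, 1L])
  wet <- a * latn + b * E[, 2L]
  tmp <- 0.92 * cld + 0.39 * b * E[, 3L]
  pre <- 0.5 * a * latn + 1.1 * b * E[, 4L]
  mk <- function(name, category, values)
    list(name = name, category = category,
         raster = gl_surface(full, matrix(values, grid$n_rows, grid$n_cols),
                             name))
  list(mk("lat", "topographic", ctr[, 2L]),
       mk("long", "topographic", ctr[, 1L]),
       mk("elev", "topographic", 2369 + 600 * E[, 5L]),
       mk("tri", "topographic", E[, 6L]),
       mk("cld", "climatic", cld),
       mk("wet", "climatic", wet),
       mk("tmp", "climatic", tmp),
       mk("pre", "climatic", pre),
       mk("ahf", "anthropogenic", E[, 7L]),
       mk("hfp", "anthropogenic", E[, 8L]))
}

#' Simulate protected-area polygons of known coverage
#'
#' Rectangles covering a known fraction of the target cells (when given) or
#' of the region otherwise, so the expected unprotected fraction is exactly
#' `1 - pa_coverage` up to one-cell quantization.
#'
#' @param config a `study_config`.
#' @param grid a `grid_spec` (required when `hotspot_cells` is given).
#' @param hotspot_cells optional row/col matrix of target cells; covered
#'   cell by cell (area-weighted prefix) in row-major order.
#' @return a `polygon_set` (empty when coverage is 0).
#' @export
simulate_protected_areas <- function(config, grid = NULL,
                                     hotspot_cells = NULL) {
  stopifnot(inherits(config, "study_config"))
  f <- config$pa_coverage
  if (f == 0)
    return(structure(list(polygons = list()), class = "polygon_set"))
  if (is.null(hotspot_cells)) {
    bb <- config$bbox
    return(ps_rect(bb[["west"]], bb[["south"]], bb[["east"]],
                   bb[["south"]] + f * (bb[["north"]] - bb[["south"]])))
  }
  stopifnot(inherits(grid, "grid_spec"))
  cells <- hotspot_cells[order(hotspot_cells[, 1L], hotspot_cells[, 2L]), ,
                         drop = FALSE]
  a <- cell_areas(grid)[cells]
  total <- sum(a)
  take <- which(cumsum(a) - a / 2 <= f * total)
  if (f >= 1) take <- seq_len(nrow(cells))
  if (!length(take))
    return(structure(list(polygons = list()), class = "polygon_set"))
  polys <- lapply(take, function(i) {
    r <- cells[i, 1L]; cc <- cells[i, 2L]
    w <- grid$west + (cc - 1) * grid$res
    n <- grid$north - (r - 1) * grid$res
    list(cbind(c(w, w + grid$res, w + grid$res, w),
               c(n - grid$res, n - grid$res, n, n)))
  })
  polygon_set(polys)
}

#' Simulate a complete study bundle
#'
#' Generates every input of the analysis: per-species aligned FASTA files,
#' the population table, boundary and protected-area GeoJSON, the
#' environmental raster stack with its manifest, and a ground-truth JSON
#' record. All outputs are deterministic functions of the config seed.
#'
#' @param config a `study_config`.
#' @param out_dir output directory (created; existing files overwritten).
#' @param resolution grid resolution for the rasters (default 2.5
#'   arc-minutes).
#' @return invisibly, a list with the in-memory objects (`datasets`,
#'   `boundary`, `protected_areas`, `rasters`, `grid`, `ground_truth`) and
#'   the written `paths`.
#' @export
simulate_study <- function(config, out_dir,
                           resolution = 2.5 / 60) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "fasta"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "rasters"), showWarnings = FALSE)
  bb <- config$bbox
  boundary <- ps_rect(bb[["west"]], bb[["south"]], bb[["east"]], bb[["north"]])
  grid <- make_grid(boundary, resolution)
  datasets <- lapply(seq_len(config$n_species), function(i)
    simulate_species_dataset(config, i))
  # population table + FASTA
  pop_rows <- list()
  fasta_paths <- character()
  for (ds in datasets) {
    fp <- file.path(out_dir, "fasta", paste0(ds$species, ".fasta"))
    writeLines(as.vector(rbind(paste0(">", names(ds$haplotypes)),
                               unname(ds$haplotypes))), fp)
    fasta_paths <- c(fasta_paths, fp)
    for (p in ds$populations) {
      pop_rows[[length(pop_rows) + 1L]] <-
        data.frame(species = ds$species, pop_id = p$pop_id,
                   lon = p$lon, lat = p$lat,
                   haplotype = names(p$counts), count = unname(p$counts))
    }
  }
  pop_tab <- do.call(rbind, pop_rows)
  pops_csv <- file.path(out_dir, "populations.csv")
  utils::write.csv(pop_tab, pops_csv, row.names = FALSE)
  boundary_path <- file.path(out_dir, "boundary.geojson")
  write_geojson(boundary, boundary_path)
  pa <- simulate_protected_areas(config)
  pa_path <- file.path(out_dir, "protected_areas.geojson")
  write_geojson(pa, pa_path)
  rasters <- simulate_environment_rasters(config, grid)
  man_rows <- lapply(rasters, function(r) {
    rp <- file.path(out_dir, "rasters", paste0(r$name, ".asc"))
    write_esri_ascii(r$raster, rp)
    data.frame(name = r$name, category = r$category,
               path = file.path("rasters", paste0(r$name, ".asc")))
  })
  manifest <- do.call(rbind, man_rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  truth <- list(gradient_direction = config$gradient_direction,
                gradient_strength = config$gradient_strength,
                base_concentration = config$base_concentration,
                climate_slope = config$climate_slope,
                pa_coverage = config$pa_coverage,
                n_small_total = sum(vapply(datasets, function(d)
                  attr(d, "n_small"), 0L)),
                populations = do.call(rbind, lapply(datasets, function(d) {
                  gt <- attr(d, "ground_truth")
                  gt$species <- d$species
                  gt
                })))
  truth_path <- file.path(out_dir, "ground_truth.json")
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), truth_path)
  invisible(list(datasets = datasets, boundary = boundary,
                 protected_areas = pa, rasters = rasters, grid = grid,
                 ground_truth = truth,
                 paths = list(fasta = fasta_paths, populations = pops_csv,
                              boundary = boundary_path, pa = pa_path,
                              manifest = manifest_path, truth = truth_path,
                              root = out_dir)))
}
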