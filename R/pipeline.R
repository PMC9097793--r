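#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Inputs are either a
#' synthetic-study spec (`simulate = study_config(...)`) or paths to real
#' inputs (`fasta_dir`, `populations`, `boundary`, `protected_areas`,
#' `manifest` pointing at category-tagged rasters).
#'
#' @param simulate optional `study_config`; when given, inputs are
#'   generated under `out_dir/inputs`.
#' @param fasta_dir,populations,boundary,protected_areas,manifest input
#'   paths (ignored when `simulate` is given). The manifest CSV has columns
#'   `name, category, path` with raster paths relative to its own
#'   directory.
#' @param out_dir results directory.
#' @param min_n sample-size filter (default 5).
#' @param resolution grid resolution in degrees (default 2.5 arc-minutes).
#' @param power IDW exponent.
#' @param pair_mode divergence pair connectivity (`"all_pairs"` or
#'   `"delaunay"`).
#' @param truncate_negative clamp negative Phi-ST on surfaces.
#' @param z_threshold hotspot SD multiple.
#' @param connectivity hotspot component connectivity (8 or 4).
#' @param n_perm Mantel permutations.
#' @param cor_threshold collinearity cut on |r|.
#' @param top_k variables kept per category after importance screening.
#' @param max_cells subsample cap for the random forest.
#' @param seed master seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, fasta_dir = NULL,
                            populations = NULL, boundary = NULL,
                            protected_areas = NULL, manifest = NULL,
                            out_dir = tempfile("divscape_run_"),
                            min_n = 5L, resolution = 2.5 / 60, power = 2,
                            pair_mode = "all_pairs",
                            truncate_negative = TRUE, z_threshold = 1.5,
                            connectivity = 8L, n_perm = 999L,
                            cor_threshold = 0.7, top_k = 2L,
                            max_cells = 10000L, seed = 42L) {
  if (is.null(simulate) &&
      (is.null(fasta_dir) || is.null(populations) || is.null(boundary)))
    .stopf("either a simulate config or input paths must be given")
  structure(list(simulate = simulate, fasta_dir = fasta_dir,
                 populations = populations, boundary = boundary,
                 protected_areas = protected_areas, manifest = manifest,
                 out_dir = out_dir, min_n = min_n, resolution = resolution,
                 power = power, pair_mode = pair_mode,
                 truncate_negative = truncate_negative,
                 z_threshold = z_threshold,
                 connectivity = as.integer(connectivity),
                 n_perm = as.integer(n_perm),
                 cor_threshold = cor_threshold, top_k = as.integer(top_k),
                 max_cells = as.integer(max_cells),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full landscape-genetics analysis
#'
#' Executes the stages in order: read/simulate inputs, sample-size filter,
#' per-population statistics, per-species diversity and divergence
#' surfaces, multi-species combination, hotspot delineation, protected-area
#' overlap, isolation by distance, variable extraction, collinearity
#' filter, importance screening, per-variable GAMs, and variation
#' partitioning. Every intermediate is written under `out_dir` and a run
#' manifest records parameters, seeds and stage outputs. Identical
#' config and seed give identical numeric outputs.
#'
#' @param config a `pipeline_config`, or a path to a YAML file whose keys
#'   are `pipeline_config()` arguments (a `simulate:` block is passed to
#'   `study_config()`).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with all stage results (`datasets`,
#'   `diversity`, `fst`, `surfaces`, `combined_hd`, `combined_fst`,
#'   `hotspots`, `protection`, `ibd`, `variable_table`, `retained`,
#'   `selected`, `gams`, `partition`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- .config_from_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  ## stage: inputs
  if (!is.null(config$simulate)) {
    say("[inputs] simulating study (seed %d)", config$simulate$seed)
    bundle <- simulate_study(config$simulate, file.path(out, "inputs"),
                             resolution = config$resolution)
    datasets <- bundle$datasets
    boundary <- bundle$boundary
    pa <- bundle$protected_areas
    rasters <- bundle$rasters
  } else {
    say("[inputs] reading study from %s", config$populations)
    tab <- utils::read.csv(config$populations, stringsAsFactors = FALSE)
    species <- unique(tab$species)
    datasets <- lapply(species, function(sp) {
      fp <- file.path(config$fasta_dir, paste0(sp, ".fasta"))
      if (!file.exists(fp)) fp <- file.path(config$fasta_dir, paste0(sp, ".fa"))
      read_species_dataset(fp, config$populations, sp)
    })
    boundary <- read_geojson(config$boundary)
    pa <- if (is.null(config$protected_areas))
      structure(list(polygons = list()), class = "polygon_set")
    else read_geojson(config$protected_areas)
    rasters <- if (is.null(config$manifest)) list() else {
      man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
      base <- dirname(config$manifest)
      lapply(seq_len(nrow(man)), function(i)
        list(name = man$name[i], category = man$category[i],
             raster = read_esri_ascii(file.path(base, man$path[i]),
                                      man$name[i])))
    }
  }

  ## stage: filter + statistics
  say("[stats] filtering N >= %d and computing diversity/Phi-ST", config$min_n)
  n_dropped <- 0L
  datasets <- lapply(datasets, function(d) {
    f <- suppressWarnings(filter_min_sample(d, config$min_n))
    n_dropped <<- n_dropped + attr(f, "n_dropped")
    f
  })
  datasets <- Filter(function(d) length(d$populations) > 0L, datasets)
  if (!length(datasets)) .stopf("stage stats: no populations retained")
  diversity <- do.call(rbind, lapply(datasets, diversity_table))
  fst <- list()
  for (d in datasets) if (length(d$populations) >= 2L)
    fst[[d$species]] <- fst_matrix(d)
  write_stats_csv(diversity, fst, file.path(out, "stats"))
  hd_pi <- index_correlation(diversity$hd, diversity$pi)

  ## stage: surfaces
  say("[landscape] interpolating %d species on the grid", length(datasets))
  grid <- make_grid(boundary, config$resolution)
  dir.create(file.path(out, "surfaces"), showWarnings = FALSE)
  hd_surfaces <- list(); fst_surfaces <- list()
  for (d in datasets) {
    dv <- diversity[diversity$species == d$species, , drop = FALSE]
    s <- species_diversity_surface(dv, grid, power = config$power)
    hd_surfaces[[d$species]] <- s
    write_esri_ascii(s, file.path(out, "surfaces",
                                  paste0("hd_", d$species, ".asc")))
    if (!is.null(fst[[d$species]])) {
      sv <- species_divergence_surface(dv, fst[[d$species]], grid,
                                       pair_mode = config$pair_mode,
                                       truncate_negative = config$truncate_negative,
                                       power = config$power)
      fst_surfaces[[d$species]] <- sv
      write_esri_ascii(sv, file.path(out, "surfaces",
                                     paste0("fst_", d$species, ".asc")))
    }
  }
  combined_hd <- combine_surfaces(hd_surfaces, "combined_hd")
  write_esri_ascii(combined_hd, file.path(out, "surfaces", "combined_hd.asc"))
  combined_fst <- if (length(fst_surfaces))
    combine_surfaces(fst_surfaces, "combined_fst") else NULL
  if (!is.null(combined_fst))
    write_esri_ascii(combined_fst, file.path(out, "surfaces", "combined_fst.asc"))

  ## stage: hotspots + protection
  say("[hotspots] z > %.2f, %d-connectivity", config$z_threshold,
      config$connectivity)
  hotspots <- detect_hotspots(combined_hd, config$z_threshold,
                              config$connectivity)
  dir.create(file.path(out, "hotspots"), showWarnings = FALSE)
  utils::write.csv(hotspot_table(hotspots),
                   file.path(out, "hotspots", "hotspots.csv"),
                   row.names = FALSE)
  write_hotspot_geojson(hotspots, file.path(out, "hotspots",
                                            "hotspots.geojson"))
  protection <- if (length(hotspots$hotspots)) {
    pr <- protected_overlap(hotspots, pa)
    utils::write.csv(pr$per_hotspot,
                     file.path(out, "hotspots", "protection.csv"),
                     row.names = FALSE)
    pr
  } else NULL

  ## stage: isolation by distance
  say("[ibd] Mantel tests, %d permutations", config$n_perm)
  ibd <- ibd_table(diversity, fst, n_perm = config$n_perm,
                   seed = .sub_seed(config$seed, 300L))
  dir.create(file.path(out, "ibd"), showWarnings = FALSE)
  utils::write.csv(ibd, file.path(out, "ibd", "ibd.csv"), row.names = FALSE)

  ## stage: attribution
  retained <- selected <- NULL; gams <- list(); partition <- NULL
  vtab <- NULL
  if (length(rasters)) {
    say("[attribute] %d candidate variables", length(rasters))
    dir.create(file.path(out, "attribution"), showWarnings = FALSE)
    vtab <- extract_variable_table(rasters, combined_hd)
    retained <- collinearity_filter(vtab, config$cor_threshold)
    writeLines(retained, file.path(out, "attribution", "retained.txt"))
    cats <- attr(vtab, "categories")
    keep_tab <- vtab
    attr(keep_tab, "categories") <- cats[retained]
    selected <- character()
    for (cat in c("climatic", "topographic", "anthropogenic")) {
      vars <- retained[cats[retained] == cat]
      if (!length(vars)) next
      sel <- if (length(vars) <= config$top_k) vars
      else importance_select(keep_tab, cat, k = config$top_k,
                             seed = .sub_seed(config$seed, 400L),
                             max_cells = config$max_cells)
      selected <- c(selected, sel)
    }
    gams <- lapply(stats::setNames(selected, selected), function(v)
      fit_gam(vtab[[v]], vtab$hd))
    gam_sum <- do.call(rbind, lapply(selected, function(v)
      data.frame(variable = v, category = unname(cats[v]),
                 r2_adj = gams[[v]]$r2_adj, edf = gams[[v]]$edf,
                 p_value = gams[[v]]$p_value, trend = gams[[v]]$trend)))
    utils::write.csv(gam_sum, file.path(out, "attribution", "gam_summary.csv"),
                     row.names = FALSE)
    sets <- list(C = selected[cats[selected] == "climatic"],
                 T = selected[cats[selected] == "topographic"],
                 A = selected[cats[selected] == "anthropogenic"])
    if (all(lengths(sets) > 0L)) {
      partition <- variation_partition(vtab, sets)
      part_df <- data.frame(fraction = c(names(partition$fractions),
                                         "residual"),
                            value = c(unname(partition$fractions),
                                      partition$residual))
      utils::write.csv(part_df, file.path(out, "attribution", "partition.csv"),
                       row.names = FALSE)
    }
  }

  ## manifest
  manifest <- list(
    package = "divscape",
    version = as.character(utils::packageVersion("divscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[c("min_n", "resolution", "power", "pair_mode",
                          "truncate_negative", "z_threshold", "connectivity",
                          "n_perm", "cor_threshold", "top_k", "max_cells")],
    n_species = length(datasets),
    n_populations = nrow(diversity),
    n_populations_dropped = n_dropped,
    hd_pi_correlation = hd_pi,
    outputs = list.files(out, recursive = TRUE),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out, "run_manifest.json"))
  say("[done] %.1f s, outputs in %s", manifest$elapsed_s, out)
  invisible(list(datasets = datasets, diversity = diversity, fst = fst,
                 hd_surfaces = hd_surfaces, fst_surfaces = fst_surfaces,
                 combined_hd = combined_hd, combined_fst = combined_fst,
                 hotspots = hotspots, protection = protection, ibd = ibd,
                 variable_table = vtab, retained = retained,
                 selected = selected, gams = gams, partition = partition,
                 n_dropped = n_dropped, grid = grid, manifest = manifest))
}

# YAML front end: top-level keys are pipeline_config() arguments; a
# `simulate:` block is passed to study_config() (its bbox given as a
# named mapping).
.config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$bbox)) sim$bbox <- unlist(sim$bbox)
    y$simulate <- do.call(study_config, sim)
  }
  do.call(pipeline_config, y)
}
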