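#' Species haplotype datasets
#'
#' A `species_dataset` couples a species' aligned haplotype pool with its
#' georeferenced population samples. Haplotypes are aligned nucleotide
#' strings (A, C, G, T, N, -) of equal length; each population holds a
#' haplotype count vector from which the per-individual sequence matrix can
#' be reconstructed by repeating each haplotype `count` times.
#'
#' @param species species name.
#' @param haplotypes named character vector of aligned sequences (names are
#'   haplotype ids, unique).
#' @param populations list of population samples; each a list with
#'   `pop_id`, `lon`, `lat` and a named non-negative integer vector
#'   `counts` over haplotype ids.
#' @return object of class `species_dataset`.
#' @export
species_dataset <- function(species, haplotypes, populations) {
  haplotypes <- toupper(unlist(haplotypes))
  if (is.null(names(haplotypes)) || anyDuplicated(names(haplotypes)))
    .stopf("haplotype ids must be unique and named")
  L <- unique(nchar(haplotypes))
  if (length(L) != 1L)
    .stopf("alignment error: haplotype sequences of species '%s' differ in length (%s)",
           species, paste(L, collapse = ", "))
  if (L < 1L) .stopf("zero-length alignment")
  bad <- grepl("[^ACGTN-]", haplotypes)
  if (any(bad))
    .stopf("invalid characters in haplotype(s): %s",
           paste(names(haplotypes)[bad], collapse = ", "))
  if (!length(populations)) .stopf("species '%s' has no populations", species)
  ids <- vapply(populations, `[[`, "", "pop_id")
  if (anyDuplicated(ids)) .stopf("duplicate population ids: %s",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  populations <- lapply(populations, function(p) {
    cnt <- p$counts
    if (is.null(names(cnt))) .stopf("population '%s': counts must be named", p$pop_id)
    if (any(cnt < 0)) .stopf("population '%s': negative haplotype count", p$pop_id)
    unknown <- setdiff(names(cnt), names(haplotypes))
    if (length(unknown))
      .stopf("population '%s' references haplotype id(s) absent from the pool: %s",
             p$pop_id, paste(unknown, collapse = ", "))
    if (abs(p$lon) > 180 || abs(p$lat) > 90)
      .stopf("population '%s': coordinates outside WGS84 bounds", p$pop_id)
    cnt <- cnt[cnt > 0]
    list(pop_id = p$pop_id, lon = as.numeric(p$lon), lat = as.numeric(p$lat),
         counts = structure(as.integer(cnt), names = names(cnt)),
         n = as.integer(sum(cnt)))
  })
  structure(list(species = species, haplotypes = haplotypes,
                 populations = populations, seq_length = as.integer(L)),
            class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  ns <- vapply(x$populations, `[[`, 1L, "n")
  cat(sprintf("species_dataset '%s': %d haplotypes (L = %d), %d populations, N total = %d\n",
              x$species, length(x$haplotypes), x$seq_length,
              length(x$populations), sum(ns)))
  invisible(x)
}

#' Read a species dataset from FASTA + population table
#'
#' The FASTA holds one record per haplotype (pre-aligned, equal length);
#' the CSV population table has columns
#' `species,pop_id,lon,lat,haplotype,count` and is aggregated by `pop_id`.
#'
#' @param fasta_path path to the aligned haplotype FASTA.
#' @param population_table path to the population CSV.
#' @param species species name selecting rows of the table.
#' @return a `species_dataset`.
#' @export
read_species_dataset <- function(fasta_path, population_table, species) {
  seqs <- ape::read.FASTA(fasta_path)
  haps <- toupper(vapply(as.character(seqs), paste, "", collapse = ""))
  tab <- utils::read.csv(population_table, stringsAsFactors = FALSE)
  need <- c("species", "pop_id", "lon", "lat", "haplotype", "count")
  if (!all(need %in% names(tab)))
    .stopf("population table must have columns %s", paste(need, collapse = ","))
  tab <- tab[tab$species == species, , drop = FALSE]
  if (!nrow(tab)) .stopf("no rows for species '%s' in %s", species, population_table)
  pops <- lapply(split(tab, factor(tab$pop_id, levels = unique(tab$pop_id))),
                 function(d) {
    cnt <- tapply(d$count, d$haplotype, sum)
    list(pop_id = d$pop_id[1L], lon = d$lon[1L], lat = d$lat[1L],
         counts = structure(as.integer(cnt), names = names(cnt)))
  })
  species_dataset(species, haps, unname(pops))
}

#' Retain populations with adequate sample size
#'
#' Keeps exactly the populations with `N >= min_n`, preserving order. When
#' everything is removed an `empty` attribute is set (with a warning) rather
#' than erroring, so multi-species loops can continue.
#'
#' @param dataset a `species_dataset`.
#' @param min_n minimum number of sampled individuals (default 5).
#' @return filtered `species_dataset`; attribute `n_dropped` counts removed
#'   populations and `empty` flags total removal.
#' @export
filter_min_sample <- function(dataset, min_n = 5L) {
  stopifnot(inherits(dataset, "species_dataset"), min_n >= 1L)
  ns <- vapply(dataset$populations, `[[`, 1L, "n")
  keep <- ns >= min_n
  out <- dataset
  out$populations <- dataset$populations[keep]
  attr(out, "n_dropped") <- sum(!keep)
  if (!any(keep)) {
    attr(out, "empty") <- TRUE
    .warnf("species '%s': all populations removed by the N >= %d filter",
           dataset$species, min_n)
  }
  out
}

#' Nei's unbiased haplotype diversity
#'
#' `H = n/(n-1) * (1 - sum p_i^2)`: the sample-size-corrected probability
#' that two randomly drawn individuals carry different haplotypes.
#'
#' @param pop a population sample (list with `counts`), or a bare named/
#'   unnamed count vector.
#' @return haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(pop) {
  counts <- if (is.list(pop)) pop$counts else pop
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) .stopf("haplotype diversity undefined for N < 2")
  p <- counts / n
  h <- n / (n - 1) * (1 - sum(p^2))
  min(max(h, 0), 1)
}

# per-pair nucleotide distances between haplotypes with pairwise deletion of
# gaps/ambiguities; returns list(diff = raw difference counts,
# prop = per-site proportions, compared = compared-site counts)
.hap_distances <- function(haplotypes) {
  ids <- names(haplotypes)
  K <- length(haplotypes)
  M <- do.call(rbind, strsplit(unname(haplotypes), ""))
  valid <- matrix(M %in% c("A", "C", "G", "T"), K)
  dif <- comp <- matrix(0, K, K, dimnames = list(ids, ids))
  if (K >= 2L) for (i in 1:(K - 1L)) for (j in (i + 1L):K) {
    both <- valid[i, ] & valid[j, ]
    comp[i, j] <- comp[j, i] <- sum(both)
    dif[i, j] <- dif[j, i] <- sum(M[i, both] != M[j, both])
  }
  prop <- dif / comp
  prop[comp == 0] <- NA_real_
  diag(prop) <- 0
  list(diff = dif, prop = prop, compared = comp)
}

#' Nucleotide diversity
#'
#' Per-site nucleotide diversity
#' `pi = n/(n-1) * sum_{i,j} p_i p_j d_ij`, with `d_ij` the proportion of
#' differing sites between haplotypes i and j over sites where both carry an
#' unambiguous base (pairwise deletion of `-`/`N`). Pairs with no comparable
#' sites are excluded with a warning.
#'
#' @param pop a population sample (list with `counts`) or named count
#'   vector over haplotype ids.
#' @param haplotypes named character vector of aligned sequences.
#' @return per-site nucleotide diversity (>= 0).
#' @export
nucleotide_diversity <- function(pop, haplotypes) {
  counts <- if (is.list(pop)) pop$counts else pop
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) .stopf("nucleotide diversity undefined for N < 2")
  unknown <- setdiff(names(counts), names(haplotypes))
  if (length(unknown))
    .stopf("unknown haplotype id(s): %s", paste(unknown, collapse = ", "))
  d <- .hap_distances(haplotypes[names(counts)])$prop
  if (any(is.na(d))) {
    .warnf("haplotype pair(s) with zero comparable sites excluded from pi")
    d[is.na(d)] <- 0
  }
  p <- counts / n
  pi_val <- n / (n - 1) * as.numeric(t(p) %*% d %*% p)
  max(pi_val, 0)
}

#' Pairwise Phi-ST between two populations
#'
#' Two-level AMOVA on squared inter-haplotype distances. With
#' `method = "distance"` (default) the squared distance between two
#' individuals is their number of differing nucleotide sites (pairwise
#' deletion of gaps/ambiguities); with `method = "frequency"` it is 0/1
#' (same/different haplotype). Phi-ST = sigma2_a / (sigma2_a + sigma2_b),
#' the among-population fraction of molecular variance. Raw values may be
#' slightly negative and are returned untruncated; when the total variance
#' is zero (both populations fixed for the same haplotype) the statistic is
#' defined as 0 and flagged with attribute `degenerate`.
#'
#' @param popA,popB population samples (lists with `counts`), both `N >= 2`.
#' @param haplotypes named character vector of aligned sequences.
#' @param method squared-distance flavor, `"distance"` or `"frequency"`.
#' @return Phi-ST (<= 1), possibly with attribute `degenerate = TRUE`.
#' @export
pairwise_phist <- function(popA, popB, haplotypes,
                           method = c("distance", "frequency")) {
  method <- match.arg(method)
  cA <- popA$counts[popA$counts > 0]; cB <- popB$counts[popB$counts > 0]
  n1 <- sum(cA); n2 <- sum(cB)
  if (n1 < 2 || n2 < 2) .stopf("Phi-ST requires N >= 2 in both populations")
  ids <- union(names(cA), names(cB))
  unknown <- setdiff(ids, names(haplotypes))
  if (length(unknown))
    .stopf("unknown haplotype id(s): %s", paste(unknown, collapse = ", "))
  d2 <- if (method == "distance") {
    hd <- .hap_distances(haplotypes[ids])
    if (length(ids) >= 2L && any(hd$compared[upper.tri(hd$compared)] == 0))
      .warnf("haplotype pair(s) with zero comparable sites treated as distance 0")
    hd$diff
  } else {
    m <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 0
    m
  }
  .phist_from_counts(cA, cB, d2)
}

# AMOVA variance components from haplotype counts and a squared-distance
# matrix over the union of haplotype ids
.phist_from_counts <- function(cA, cB, d2) {
  ids <- rownames(d2)
  xa <- xb <- structure(numeric(length(ids)), names = ids)
  xa[names(cA)] <- cA; xb[names(cB)] <- cB
  n1 <- sum(xa); n2 <- sum(xb); N <- n1 + n2
  tot <- xa + xb
  ss_tot <- as.numeric(t(tot) %*% d2 %*% tot) / 2 / N
  ss_a <- as.numeric(t(xa) %*% d2 %*% xa) / 2 / n1
  ss_b <- as.numeric(t(xb) %*% d2 %*% xb) / 2 / n2
  ss_within <- ss_a + ss_b
  ss_among <- ss_tot - ss_within
  df_within <- N - 2
  sigma_b <- ss_within / df_within
  n_c <- N - (n1^2 + n2^2) / N  # AMOVA coefficient, P = 2 groups
  sigma_a <- (ss_among / 1 - sigma_b) / n_c
  denom <- sigma_a + sigma_b
  if (abs(denom) < 1e-12) return(structure(0, degenerate = TRUE))
  min(sigma_a / denom, 1)
}

#' Pairwise Phi-ST matrix for all retained populations
#'
#' @param dataset a `species_dataset` with at least two populations.
#' @param method passed to [pairwise_phist()].
#' @return object of class `phist_matrix`: list with `pop_ids` and a
#'   symmetric `values` matrix (diagonal 0, raw negatives kept).
#' @export
fst_matrix <- function(dataset, method = c("distance", "frequency")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "species_dataset"))
  pops <- dataset$populations
  if (length(pops) < 2L) .stopf("need >= 2 populations for a Phi-ST matrix")
  ids <- vapply(pops, `[[`, "", "pop_id")
  # distances over the full pool once, reused for every pair
  d2_all <- if (method == "distance") {
    .hap_distances(dataset$haplotypes)$diff
  } else {
    m <- matrix(1, length(dataset$haplotypes), length(dataset$haplotypes),
                dimnames = list(names(dataset$haplotypes),
                                names(dataset$haplotypes)))
    diag(m) <- 0
    m
  }
  P <- length(pops)
  V <- matrix(0, P, P, dimnames = list(ids, ids))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    u <- union(names(pops[[i]]$counts), names(pops[[j]]$counts))
    V[i, j] <- V[j, i] <-
      as.numeric(.phist_from_counts(pops[[i]]$counts, pops[[j]]$counts,
                                    d2_all[u, u, drop = FALSE]))
  }
  structure(list(pop_ids = ids, values = V, species = dataset$species,
                 method = method),
            class = "phist_matrix")
}

#' @export
print.phist_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("phist_matrix (%s): %d populations of '%s'; Phi-ST range [%.3f, %.3f]\n",
              x$method, length(x$pop_ids), x$species,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Per-population diversity table
#'
#' One row per population with coordinates, sample size, Nei's unbiased
#' haplotype diversity and per-site nucleotide diversity.
#'
#' @param dataset a `species_dataset` (populations should already satisfy
#'   the sample-size filter; rows need `N >= 2`).
#' @return data frame with columns
#'   `species, pop_id, lon, lat, n, hd, pi`.
#' @export
diversity_table <- function(dataset) {
  stopifnot(inherits(dataset, "species_dataset"))
  rows <- lapply(dataset$populations, function(p) {
    data.frame(species = dataset$species, pop_id = p$pop_id,
               lon = p$lon, lat = p$lat, n = p$n,
               hd = haplotype_diversity(p),
               pi = nucleotide_diversity(p, dataset$haplotypes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two diversity indices
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return list with `r` (Pearson correlation) and `p` (two-sided t-test).
#' @export
index_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    .stopf("need two equal-length vectors with >= 3 values")
  if (any(!is.finite(x)) || any(!is.finite(y))) .stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Write diversity and differentiation outputs as CSV
#'
#' @param diversity a diversity table (from [diversity_table()]).
#' @param fst a `phist_matrix` or list of them.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_stats_csv <- function(diversity, fst, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(out_dir, "diversity.csv")
  utils::write.csv(diversity, p, row.names = FALSE)
  paths <- c(paths, p)
  if (inherits(fst, "phist_matrix")) fst <- list(fst)
  for (fm in fst) {
    tag <- gsub("[^A-Za-z0-9_.-]", "_", fm$species)
    sq <- file.path(out_dir, sprintf("phist_%s_square.csv", tag))
    utils::write.csv(fm$values, sq)
    idx <- which(upper.tri(fm$values), arr.ind = TRUE)
    long <- data.frame(pop_i = fm$pop_ids[idx[, 1L]],
                       pop_j = fm$pop_ids[idx[, 2L]],
                       phist = fm$values[idx])
    lg <- file.path(out_dir, sprintf("phist_%s_long.csv", tag))
    utils::write.csv(long, lg, row.names = FALSE)
    paths <- c(paths, sq, lg)
  }
  invisible(paths)
}
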