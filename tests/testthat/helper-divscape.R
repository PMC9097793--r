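# fixtures and independent oracles used across test files

# random haplotype pool: K aligned sequences of length L
rand_haps <- function(K, L, gap_frac = 0) {
  alphabet <- c("A", "C", "G", "T")
  haps <- vapply(seq_len(K), function(k) {
    s <- sample(alphabet, L, replace = TRUE)
    if (gap_frac > 0) {
      ng <- rbinom(1L, L, gap_frac)
      if (ng > 0) s[sample.int(L, ng)] <- sample(c("-", "N"), ng, replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
  names(haps) <- sprintf("h%02d", seq_len(K))
  haps
}

make_pop <- function(pop_id, counts, lon = 0, lat = 0) {
  list(pop_id = pop_id, lon = lon, lat = lat,
       counts = structure(as.integer(counts), names = names(counts)))
}

# expand a count vector into one sequence per individual
expand_individuals <- function(counts, haplotypes) {
  rep(unname(haplotypes[names(counts)]), times = counts)
}

# per-pair distances between two sequences: list(diff, compared, prop)
seq_pair_dist <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  list(diff = sum(av[ok] != bv[ok]), compared = sum(ok),
       prop = if (sum(ok)) sum(av[ok] != bv[ok]) / sum(ok) else NA_real_)
}

# brute-force nucleotide diversity: average per-site difference over all
# individual pairs (unbiased form via n/(n-1) frequency weighting is
# equivalent; this is the plain pair average)
oracle_pi <- function(counts, haplotypes) {
  seqs <- expand_individuals(counts, haplotypes)
  n <- length(seqs)
  tot <- 0; npair <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- seq_pair_dist(seqs[i], seqs[j])$prop
    if (!is.na(d)) { tot <- tot + d; npair <- npair + 1L }
  }
  tot / npair
}

# textbook two-level AMOVA from expanded individuals and explicit
# sum-of-squares loops (independent of the package's count-weighted path)
oracle_phist <- function(countsA, countsB, haplotypes,
                         method = c("distance", "frequency")) {
  method <- match.arg(method)
  sa <- expand_individuals(countsA, haplotypes)
  sb <- expand_individuals(countsB, haplotypes)
  # squared distance between individuals i, j
  d2 <- function(x, y) {
    if (method == "frequency") return(as.numeric(x != y))
    if (x == y) return(0)
    seq_pair_dist(x, y)$diff
  }
  all_seqs <- c(sa, sb)
  N <- length(all_seqs); n1 <- length(sa); n2 <- length(sb)
  ss <- function(seqs) {
    m <- length(seqs); tot <- 0
    if (m >= 2L) for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      tot <- tot + d2(seqs[i], seqs[j])
    tot / m
  }
  ss_total <- ss(all_seqs)
  ss_within <- ss(sa) + ss(sb)
  ss_among <- ss_total - ss_within
  sigma_b <- ss_within / (N - 2)
  n_c <- N - (n1^2 + n2^2) / N
  sigma_a <- (ss_among / 1 - sigma_b) / n_c
  if (abs(sigma_a + sigma_b) < 1e-12) return(0)
  sigma_a / (sigma_a + sigma_b)
}

# all permutations of 1..n built independently of the package (filtered
# tuples); n kept tiny
oracle_perms <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
}

# random small species dataset for property tests
rand_dataset <- function(n_pops = 3L, K = 4L, L = 40L, n_range = c(2L, 8L),
                         gap_frac = 0) {
  haps <- rand_haps(K, L, gap_frac)
  pops <- lapply(seq_len(n_pops), function(i) {
    n <- sample(n_range[1L]:n_range[2L], 1L)
    k <- sample.int(K, sample.int(K, 1L))
    cnt <- as.integer(rmultinom(1L, n, rep(1, length(k))))
    names(cnt) <- names(haps)[k]
    make_pop(sprintf("p%d", i), cnt[cnt > 0],
             lon = runif(1, 0, 10), lat = runif(1, 0, 10))
  })
  species_dataset("sp_test", haps, pops)
}

# tiny study config for fast end-to-end fixtures
small_config <- function(seed = 1L, ...) {
  study_config(bbox = c(west = 100, east = 103, south = 24, north = 27),
               n_species = 3L, pops_range = c(6L, 10L), seed = seed, ...)
}
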