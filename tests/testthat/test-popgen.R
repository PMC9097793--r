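# population genetic statistics: H_D, pi, Phi-ST and their oracles

test_that("dataset reading reconstructs populations from FASTA and table", {
  dir <- withr::local_tempdir()
  writeLines(c(">h1", "ACGTACGTAC"), file.path(dir, "sp.fasta"))
  write.csv(data.frame(species = "sp", pop_id = "p1", lon = 100, lat = 25,
                       haplotype = "h1", count = 5),
            file.path(dir, "pops.csv"), row.names = FALSE)
  ds <- read_species_dataset(file.path(dir, "sp.fasta"),
                             file.path(dir, "pops.csv"), "sp")
  expect_equal(length(ds$populations), 1L)
  expect_equal(ds$populations[[1]]$n, 5L)
  rows <- rep(ds$haplotypes[["h1"]], ds$populations[[1]]$counts[["h1"]])
  expect_equal(rows, rep("ACGTACGTAC", 5))

  # unknown haplotype id is named in the error
  write.csv(data.frame(species = "sp", pop_id = "p1", lon = 100, lat = 25,
                       haplotype = "h9", count = 5),
            file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_species_dataset(file.path(dir, "sp.fasta"),
                                    file.path(dir, "bad.csv"), "sp"), "h9")

  # negative counts and ragged alignments are rejected
  write.csv(data.frame(species = "sp", pop_id = "p1", lon = 100, lat = 25,
                       haplotype = "h1", count = -2),
            file.path(dir, "neg.csv"), row.names = FALSE)
  expect_error(read_species_dataset(file.path(dir, "sp.fasta"),
                                    file.path(dir, "neg.csv"), "sp"),
               "negative")
  writeLines(c(">h1", "ACGT", ">h2", "ACGTAA"), file.path(dir, "rag.fasta"))
  expect_error(read_species_dataset(file.path(dir, "rag.fasta"),
                                    file.path(dir, "pops.csv"), "sp"),
               "length")
})

test_that("round trip through a simulated bundle preserves sample sizes", {
  dir <- withr::local_tempdir()
  bundle <- simulate_study(study_config(n_species = 2L,
                                        pops_range = c(5L, 8L), seed = 1L),
                           dir, resolution = 0.5)
  tab <- read.csv(bundle$paths$populations)
  for (sp in unique(tab$species)) {
    ds <- read_species_dataset(file.path(dir, "fasta", paste0(sp, ".fasta")),
                               bundle$paths$populations, sp)
    # independent recomputation of N from the CSV
    expected <- tapply(tab$count[tab$species == sp],
                       tab$pop_id[tab$species == sp], sum)
    got <- sapply(ds$populations, `[[`, "n")
    names(got) <- sapply(ds$populations, `[[`, "pop_id")
    expect_equal(got[names(expected)], expected,
                 ignore_attr = TRUE)
    expect_equal(sum(got), sum(tab$count[tab$species == sp]))
  }
})

test_that("sample-size filter keeps exactly the populations with N >= min_n", {
  haps <- structure(c("AAAA", "AATT"), names = c("h1", "h2"))
  pops <- list(make_pop("a", c(h1 = 2L, h2 = 2L)),
               make_pop("b", c(h1 = 5L)),
               make_pop("c", c(h1 = 3L, h2 = 3L)))
  ds <- species_dataset("sp", haps, pops)
  f <- filter_min_sample(ds, 5L)
  expect_equal(sapply(f$populations, `[[`, "pop_id"), c("b", "c"))
  expect_equal(attr(f, "n_dropped"), 1L)
  # min_n = 1 is the identity
  f1 <- filter_min_sample(ds, 1L)
  expect_equal(length(f1$populations), 3L)
  # total removal warns and flags rather than erroring
  expect_warning(f0 <- filter_min_sample(ds, 100L), "removed")
  expect_true(attr(f0, "empty"))

  # contaminated synthetic study: retained count equals a brute-force scan
  set.seed(7)
  ds7 <- simulate_species_dataset(small_config(seed = 7L, contaminate = TRUE,
                                               n_small = 4L), 1L)
  ns <- sapply(ds7$populations, `[[`, "n")
  f7 <- filter_min_sample(ds7, 5L)
  expect_equal(length(f7$populations), sum(ns >= 5L))
  expect_equal(attr(f7, "n_dropped"), sum(ns < 5L))
})

test_that("haplotype diversity matches Nei's unbiased estimator", {
  expect_equal(haplotype_diversity(c(h1 = 10L)), 0)
  expect_equal(haplotype_diversity(c(a = 1L, b = 1L, c = 1L, d = 1L, e = 1L)), 1)
  # hand evaluation: counts {3,2,1}, n = 6 -> (6/5)(1 - 14/36) = 11/15
  expect_equal(haplotype_diversity(c(x = 3L, y = 2L, z = 1L)), 11 / 15)
  expect_error(haplotype_diversity(c(h1 = 1L)), "N < 2")
})

test_that("haplotype diversity bounds and boundary cases hold on random input", {
  set.seed(101)
  for (i in 1:1000) {
    K <- sample(1:6, 1L)
    cnt <- structure(rmultinom(1L, sample(2:30, 1L), rep(1, K))[, 1L],
                     names = paste0("h", 1:K))
    cnt <- cnt[cnt > 0]
    h <- haplotype_diversity(cnt)
    expect_gte(h, 0); expect_lte(h, 1)
    if (all(cnt == 1L)) expect_equal(h, 1)
    if (length(cnt) == 1L) expect_equal(h, 0)
    if (h == 1) expect_true(all(cnt == 1L))
    if (h == 0) expect_true(length(cnt) == 1L)
  }
})

test_that("statistics are invariant to haplotype relabeling and row order", {
  set.seed(11)
  for (i in 1:20) {
    ds <- rand_dataset(n_pops = 3L, n_range = c(3L, 8L))
    perm <- sample(names(ds$haplotypes))
    relabel <- structure(paste0("z", seq_along(perm)), names = perm)
    haps2 <- ds$haplotypes[perm]
    names(haps2) <- relabel[perm]
    pops2 <- lapply(rev(ds$populations), function(p) {
      cnt <- p$counts[sample(seq_along(p$counts))]
      names(cnt) <- relabel[names(cnt)]
      list(pop_id = p$pop_id, lon = p$lon, lat = p$lat, counts = cnt)
    })
    ds2 <- species_dataset("sp_test", haps2, pops2)
    for (k in seq_along(ds$populations)) {
      p1 <- ds$populations[[k]]
      p2 <- ds2$populations[[length(ds$populations) + 1L - k]]
      expect_equal(haplotype_diversity(p1), haplotype_diversity(p2),
                   tolerance = 1e-14)
      expect_equal(nucleotide_diversity(p1, ds$haplotypes),
                   nucleotide_diversity(p2, ds2$haplotypes),
                   tolerance = 1e-14)
    }
  }
})

test_that("nucleotide diversity matches hand values and pair-enumeration oracle", {
  # two haplotypes at p = q = 0.5 differing at 1 of 10 sites, n = 4
  haps <- c(h1 = "AAAAAAAAAA", h2 = "CAAAAAAAAA")
  expect_equal(nucleotide_diversity(c(h1 = 2L, h2 = 2L), haps),
               (4 / 3) * 2 * 0.25 * 0.1)
  expect_equal(nucleotide_diversity(c(h1 = 4L), haps), 0)

  # the n/(n-1)-weighted frequency formula equals exhaustive pair averaging
  set.seed(42)
  for (i in 1:200) {
    ds <- rand_dataset(n_pops = 1L, K = sample(2:5, 1L), L = 30L,
                       n_range = c(2L, 8L),
                       gap_frac = if (i %% 4 == 0) 0.1 else 0)
    p <- ds$populations[[1]]
    expect_equal(nucleotide_diversity(p, ds$haplotypes),
                 oracle_pi(p$counts, ds$haplotypes), tolerance = 1e-12)
  }
})

test_that("Phi-ST endpoints: fixed-different pairs give 1, shared fixation gives 0", {
  haps <- c(h1 = "AAAA", h2 = "TTTT")
  a <- make_pop("a", c(h1 = 5L)); b <- make_pop("b", c(h2 = 5L))
  expect_equal(as.numeric(pairwise_phist(a, b, haps)), 1)
  same <- pairwise_phist(a, make_pop("c", c(h1 = 7L)), haps)
  expect_equal(as.numeric(same), 0)
  expect_true(attr(same, "degenerate"))
  # identical polymorphic compositions: among-population SS is zero, so the
  # unbiased estimator is at or below zero
  p1 <- make_pop("p1", c(h1 = 3L, h2 = 3L))
  p2 <- make_pop("p2", c(h1 = 3L, h2 = 3L))
  expect_lte(as.numeric(pairwise_phist(p1, p2, haps)), 0)
})

test_that("Phi-ST equals the AMOVA sums-of-squares oracle on random instances", {
  set.seed(303)
  for (i in 1:100) {
    method <- if (i %% 2 == 0) "distance" else "frequency"
    ds <- rand_dataset(n_pops = 2L, K = sample(2:4, 1L), L = 25L,
                       n_range = c(2L, 8L))
    a <- ds$populations[[1]]; b <- ds$populations[[2]]
    got <- as.numeric(pairwise_phist(a, b, ds$haplotypes, method = method))
    want <- oracle_phist(a$counts, b$counts, ds$haplotypes, method = method)
    expect_equal(got, want, tolerance = 1e-10)
    # symmetry and range
    expect_equal(got, as.numeric(pairwise_phist(b, a, ds$haplotypes,
                                                method = method)),
                 tolerance = 1e-12)
    expect_lte(got, 1)
  }
})

test_that("Phi-ST increases monotonically from shared fixation to fixed-different", {
  haps <- c(h1 = "AAAAAAAA", h2 = "TTTTAAAA")
  n <- 10L
  vals <- sapply(0:n, function(k) {
    a <- make_pop("a", c(h1 = n))
    cnt <- c(h1 = n - k, h2 = k)
    b <- make_pop("b", cnt[cnt > 0])
    as.numeric(pairwise_phist(a, b, haps))
  })
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(vals[1], 0)
  expect_equal(vals[n + 1], 1)
})

test_that("fst_matrix is symmetric, zero-diagonal and consistent with pairwise calls", {
  haps <- c(h1 = "AAAA", h2 = "TTTT")
  ds <- species_dataset("sp", haps,
                        list(make_pop("a", c(h1 = 5L)),
                             make_pop("b", c(h1 = 5L)),
                             make_pop("c", c(h2 = 5L))))
  M <- fst_matrix(ds)$values
  expect_equal(diag(M), c(a = 0, b = 0, c = 0))
  expect_equal(sort(M[upper.tri(M)]), c(0, 1, 1))

  set.seed(3)
  ds2 <- rand_dataset(n_pops = 5L, n_range = c(2L, 8L))
  M2 <- fst_matrix(ds2)
  expect_equal(M2$values, t(M2$values))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(M2$values[i, j],
                 as.numeric(pairwise_phist(ds2$populations[[i]],
                                           ds2$populations[[j]],
                                           ds2$haplotypes)),
                 tolerance = 1e-12)
  }
  expect_error(fst_matrix(species_dataset("sp", haps,
                                          list(make_pop("a", c(h1 = 5L))))),
               ">= 2 populations")
})

test_that("index correlation matches the direct covariance formula", {
  x <- 1:10
  expect_equal(index_correlation(x, x)$r, 1)
  expect_equal(index_correlation(x, -x)$r, -1)
  set.seed(11)
  a <- rnorm(50); b <- a + 0.5 * rnorm(50)
  got <- index_correlation(a, b)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, direct, tolerance = 1e-12)
  expect_lt(got$p, 0.01)
  expect_error(index_correlation(rep(1, 5), 1:5), "zero variance")
})
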