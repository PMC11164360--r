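make_sorted <- function(dt, chromsizes = c(chrZ = 10000L)) {
  sort_pairs(flip_pairs(dt, chromsizes), chromsizes)
}

test_that("the fixed-radius rule defines neighbours per side", {
  dt <- data.table::data.table(
    readID = c("a", "b"), chrom1 = "chrZ", pos1 = c(100L, 101L),
    chrom2 = "chrZ", pos2 = c(500L, 502L), strand1 = "+", strand2 = "-",
    pair_type = "UU"
  )
  p <- make_sorted(dt)
  expect_identical(find_duplicate_clusters(p, max_mismatch = 3L),
                   c(1L, 1L))
  expect_identical(find_duplicate_clusters(p, max_mismatch = 1L),
                   c(1L, 2L))
  # opposite strand1 never clusters
  dt2 <- data.table::copy(dt)[, strand1 := c("+", "-")]
  expect_identical(find_duplicate_clusters(make_sorted(dt2), 3L),
                   c(1L, 2L))
})

test_that("clusters equal the brute-force transitive closure", {
  for (seed in 1:8) {
    n <- sample(c(100L, 400L, 1200L), 1L)
    r <- sample(c(0L, 1L, 3L, 5L), 1L)
    p <- random_dedup_instance(n, seed = seed)
    expect_identical(find_duplicate_clusters(p, r),
                     oracle_dedup_clusters(p, r),
                     label = sprintf("seed %d n %d r %d", seed, n, r))
  }
})

test_that("extra match columns split otherwise identical clusters", {
  dt <- data.table::data.table(
    readID = c("a", "b"), chrom1 = "chrZ", pos1 = 100L,
    chrom2 = "chrZ", pos2 = 500L, strand1 = "+", strand2 = "-",
    pair_type = "UU", phase1 = c("0", "1")
  )
  expect_identical(find_duplicate_clusters(dt, 3L), c(1L, 1L))
  expect_identical(find_duplicate_clusters(dt, 3L,
                                           match_extras = "phase1"),
                   c(1L, 2L))
})

test_that("dedup keeps the first record of each cluster and marks the rest DD", {
  dt <- data.table::data.table(
    readID = c("a", "b", "c"), chrom1 = "chrZ", pos1 = 100L,
    chrom2 = "chrZ", pos2 = 500L, strand1 = "+", strand2 = "-",
    pair_type = "UU"
  )
  p <- make_sorted(dt)
  res <- dedup_pairs(p, c(chrZ = 10000L))
  expect_identical(nrow(res$unique), 1L)
  expect_identical(res$duplicates$pair_type, c("DD", "DD"))
  expect_identical(res$stats$duplicates, 2L)
})

test_that("null and multi-mapped classes pass through untouched", {
  dt <- data.table::data.table(
    readID = c("a", "b", "c"),
    chrom1 = c("chrZ", "chrZ", "!"),
    pos1 = c(100L, 100L, 0L),
    chrom2 = c("chrZ", "chrZ", "chrZ"),
    pos2 = c(500L, 500L, 7L),
    strand1 = c("+", "+", "."),
    strand2 = c("-", "-", "+"),
    pair_type = c("UU", "MU", "NU")
  )
  p <- sort_pairs(dt, c(chrZ = 10000L))
  res <- dedup_pairs(p, c(chrZ = 10000L))
  expect_identical(nrow(res$unmapped), 2L)
  expect_identical(nrow(res$unique), 1L)
  # conservation
  expect_identical(nrow(res$unique) + nrow(res$duplicates) +
                     nrow(res$unmapped), nrow(p))
})

test_that("output is invariant under the chunk size", {
  p <- random_dedup_instance(800, genome_size = 3000L, seed = 4)
  whole <- dedup_pairs(p, c(chrZ = 10000L), max_mismatch = 3L)
  for (cs in c(1L, 7L, 100L, 1000000L)) {
    chunked <- dedup_pairs(p, c(chrZ = 10000L), max_mismatch = 3L,
                           chunk_size = cs)
    expect_identical(chunked$unique, whole$unique,
                     label = paste("chunk", cs))
    expect_identical(chunked$duplicates, whole$duplicates,
                     label = paste("chunk dups", cs))
  }
})

test_that("duplicates straddling a chunk boundary are still found", {
  dt <- data.table::data.table(
    readID = sprintf("r%d", 1:5),
    chrom1 = "chrZ", pos1 = c(100L, 101L, 102L, 5000L, 5001L),
    chrom2 = "chrZ", pos2 = c(500L, 501L, 502L, 900L, 901L),
    strand1 = "+", strand2 = "-", pair_type = "UU"
  )
  p <- sort_pairs(dt, c(chrZ = 10000L))
  res2 <- dedup_pairs(p, c(chrZ = 10000L), chunk_size = 2L)
  res_all <- dedup_pairs(p, c(chrZ = 10000L))
  expect_identical(res2$unique, res_all$unique)
  expect_identical(nrow(res_all$unique), 2L)
})

test_that("unsorted input is rejected", {
  p <- random_dedup_instance(50, seed = 1)[50:1]
  expect_error(dedup_pairs(p, c(chrZ = 10000L)), "not sorted")
})

test_that("simulated duplicates are removed down to the true molecule count", {
  cfg <- sim_config(seed = 31, chromosomes = c(chr1 = 500000L,
                                               chr2 = 500000L),
                    n_molecules = 1500, duplication_rate = 0.5)
  lib <- simulate_library(cfg)
  res <- parse_pairs(lib$sam, lib$genome$chromsizes, parse_config())
  srt <- sort_pairs(res$pairs, res$header)
  dd <- dedup_pairs(srt, res$header)
  expect_identical(nrow(dd$unique), cfg$n_molecules)
})

test_that("complexity inverts the with-replacement sampling model", {
  # forward check: the returned pool size reproduces the observation
  est <- estimate_complexity(200, 100)
  expect_false(is.na(est$estimate))
  expect_equal(est$estimate * (1 - exp(-200 / est$estimate)), 100,
               tolerance = 1e-6)
  expect_equal(est$estimate, 125.6, tolerance = 1e-2)

  # no duplicates observed: undefined
  expect_true(is.na(estimate_complexity(100, 100)$estimate))

  # saturation: estimate collapses onto the observed distinct count
  expect_equal(estimate_complexity(1000, 10)$estimate, 10, tolerance = 1e-3)

  expect_error(estimate_complexity(10, 20), "exceed")
})

test_that("complexity recovers a known pool size from resampling", {
  C <- 5000L
  T_ <- 12500L
  set.seed(123)
  draws <- sample.int(C, T_, replace = TRUE)
  est <- estimate_complexity(T_, length(unique(draws)))
  expect_lt(abs(est$estimate - C) / C, 0.05)
})
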