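test_that("counting tallies types, cis/trans and distance tiers", {
  h <- fix_header()
  dt <- data.table::data.table(
    readID = c("a", "b", "c", "d"),
    chrom1 = c("chr1", "chr1", "chr1", "!"),
    pos1 = c(1000L, 1000L, 1000L, 0L),
    chrom2 = c("chr1", "chr1", "chr2", "!"),
    pos2 = c(1500L, 6000L, 2000L, 0L),
    strand1 = c("+", "+", "+", "."),
    strand2 = c("-", "-", "-", "."),
    pair_type = c("UU", "UU", "UU", "NN")
  )
  s <- compute_stats(dt, h, with_scaling = FALSE)
  expect_identical(s$total, 4L)
  expect_identical(s$total_mapped, 3L)
  expect_identical(s$total_unmapped, 1L)
  expect_identical(s$cis, 2L)
  expect_identical(s$trans, 1L)
  expect_identical(s$`cis_1kb+`, 1L)
  expect_identical(s$`cis_4kb+`, 1L)
  expect_identical(s$`cis_10kb+`, 0L)
  expect_identical(s$pair_types$UU, 3L)
  expect_identical(s$chrom_freq$chr1$chr2, 1L)
  # tier counts monotone non-increasing
  tiers <- unlist(s[grep("^cis_.*\\+$", names(s))])
  expect_false(is.unsorted(rev(tiers)))
})

test_that("empty input produces an all-zero summary", {
  h <- fix_header()
  s <- compute_stats(random_pairs(0)[0], h)
  expect_identical(s$total, 0L)
  expect_identical(s$cis, 0L)
  expect_identical(s$total_dups, 0L)
})

test_that("single-pass totals balance", {
  cfg <- sim_config(seed = 8, n_molecules = 2000, duplication_rate = 0.3,
                    walk_fraction = 0.05)
  lib <- simulate_library(cfg)
  res <- parse_pairs(lib$sam, lib$genome$chromsizes, parse_config())
  dd <- dedup_pairs(sort_pairs(res$pairs, res$header), res$header)
  all <- data.table::rbindlist(list(dd$unique, dd$duplicates, dd$unmapped),
                               use.names = TRUE)
  s <- compute_stats(all, res$header, with_scaling = FALSE)
  expect_identical(s$total, nrow(all))
  expect_identical(s$cis + s$trans, s$total_nodups)
  expect_identical(Reduce(`+`, s$pair_types), s$total)
  expect_identical(s$total_dups, nrow(dd$duplicates))
})

test_that("scaling bins a single cis pair into the right cell", {
  h <- fix_header()
  dt <- data.table::data.table(
    readID = "a", chrom1 = "chr1", pos1 = 1000L, chrom2 = "chr1",
    pos2 = 2500L, strand1 = "+", strand2 = "-", pair_type = "UU"
  )
  curve <- compute_scaling(dt, h, min_dist = 10, max_dist = 10000)
  hit <- curve$bins[bin_start <= 1500 & bin_end > 1500]
  expect_identical(hit$`n_+-`, 1L)
  expect_identical(sum(curve$bins$total), 1L)
  expect_identical(curve$n_trans, 0L)
})

test_that("scaling mass equals the cis pairs in range; trans feeds the average", {
  recs <- random_pairs(2000, seed = 12)
  h <- fix_header()
  curve <- compute_scaling(recs, h, min_dist = 10)
  cis <- recs[chrom1 == chrom2 & pos2 - pos1 >= 10]
  expect_identical(sum(curve$bins$total), nrow(cis))
  trans_only <- recs[chrom1 != chrom2]
  c2 <- compute_scaling(trans_only, h, min_dist = 10)
  expect_identical(sum(c2$bins$total), 0L)
  expect_gt(c2$avg_trans_frequency, 0)
})

test_that("uniform orientations are statistically similar in every bin", {
  set.seed(99)
  p <- planted_convergence_pairs(50000, s_star = 0)  # no skew anywhere
  curve <- compute_scaling(p, c(chrA = 2000000L), min_dist = 100,
                           max_dist = 1e6)
  conv <- convergence_distance(curve)
  expect_identical(conv, curve$bins$bin_start[1])
})

test_that("an everywhere-divergent curve never converges", {
  set.seed(100)
  p <- planted_convergence_pairs(50000, s_star = Inf)  # skew at all s
  curve <- compute_scaling(p, c(chrA = 2000000L), min_dist = 100,
                           max_dist = 1e6)
  expect_true(is.na(convergence_distance(curve)))
})

test_that("planted orientation skew below s* is located within one bin", {
  set.seed(101)
  p <- planted_convergence_pairs(100000, s_star = 2000)
  curve <- compute_scaling(p, c(chrA = 2000000L), min_dist = 100,
                           max_dist = 1e6)
  conv <- convergence_distance(curve)
  expect_false(is.na(conv))
  expect_lt(abs(log10(conv) - log10(2000)), 1 / 8 + 1e-9)
})

test_that("stats round-trip through YAML and TSV", {
  cfg <- sim_config(seed = 14, n_molecules = 1000)
  lib <- simulate_library(cfg)
  res <- parse_pairs(lib$sam, lib$genome$chromsizes, parse_config())
  h <- res$header
  s <- compute_stats(res$pairs, h)

  yml <- withr::local_tempfile(fileext = ".yml")
  write_stats(s, yml, "yaml")
  s_y <- read_stats(yml, "yaml")
  expect_equal(s_y$total, s$total)
  expect_equal(s_y$summary$dist_freq_convergence$convergence_dist,
               s$summary$dist_freq_convergence$convergence_dist)
  expect_equal(unlist(s_y$dist_freq), unlist(s$dist_freq))

  tsv <- withr::local_tempfile(fileext = ".stats")
  write_stats(s, tsv, "tsv")
  s_t <- read_stats(tsv, "tsv")
  flat_in <- unlist(pairsuite:::.flatten_stats(unclass(s)))
  flat_out <- unlist(pairsuite:::.flatten_stats(unclass(s_t)))
  expect_equal(flat_out[names(flat_in)], flat_in, tolerance = 1e-12)

  # the grep-able key path used in shell pipelines
  lines <- readLines(tsv)
  hit <- grep("^summary/dist_freq_convergence/convergence_dist\t", lines,
              value = TRUE)
  expect_length(hit, 1L)
  expect_equal(as.numeric(strsplit(hit, "\t")[[1]][2]),
               s$summary$dist_freq_convergence$convergence_dist)
})

test_that("unknown stats formats are rejected", {
  s <- compute_stats(random_pairs(5), fix_header(), with_scaling = FALSE)
  expect_error(write_stats(s, withr::local_tempfile(), "xml"))
})
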