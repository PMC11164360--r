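all_policies <- c("mask", "all", "5unique", "5any", "3unique", "3any")

test_that("the eight chimeric-read scenarios produce the documented pairs", {
  for (nm in names(s1_scenarios())) {
    sc <- s1_scenarios()[[nm]]
    policies <- if (!is.null(sc$expect$all_policies)) all_policies
    else names(sc$expect)
    for (pol in policies) {
      want <- if (!is.null(sc$expect$all_policies)) sc$expect$all_policies
      else sc$expect[[pol]]
      got <- s1_parse(sc, pol)
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE,
                   label = paste("scenario", nm, "policy", pol))
    }
  }
})

test_that("single-junction molecules are reported identically by all policies", {
  for (nm in c("a", "b_one_sided", "c_multi", "d_rescue")) {
    sc <- s1_scenarios()[[nm]]
    outs <- lapply(all_policies, function(p) s1_parse(sc, p))
    for (o in outs[-1]) expect_equal(o, outs[[1]])
  }
})

test_that("policy all conserves junction counts (records = segments - 1)", {
  # three-ligation molecule without and with readthrough duplication
  expect_identical(nrow(s1_parse(s1_scenarios()$f_three_ligations, "all")),
                   3L)
  expect_identical(nrow(s1_parse(s1_scenarios()$g_readthrough, "all")), 3L)
  # two-junction walk
  expect_identical(nrow(s1_parse(s1_scenarios()$e_walk, "all")), 2L)
  # under policy all, records of one read share its id and carry the
  # junction ordinal
  sc <- s1_scenarios()$f_three_ligations
  res <- parse_pairs(c(sam_header_lines(), sc$sam), fix_chromsizes,
                     parse_config(walk_policy = "all"))
  expect_true("walk_pair_index" %in% names(res$pairs))
  expect_identical(res$pairs$walk_pair_index, 1:3)
  expect_identical(unique(res$pairs$readID), "f")
})

test_that("rescue requires convergent geometry within the molecule size", {
  base <- function(green_chrom, green_pos, green_cigar, blue_flag = 129) {
    c(sam_line("x", 65, "chr1", 1000, 60, "50M50S"),
      sam_line("x", 2129, green_chrom, green_pos, 60, green_cigar),
      sam_line("x", blue_flag, "chr1", 4900, 60, "100M"))
  }
  parse1 <- function(sam) {
    parse_pairs(c(sam_header_lines(), sam), fix_chromsizes,
                parse_config(walk_policy = "mask"))$pairs
  }
  # in range, opposite strands, cis -> rescued
  expect_identical(parse1(base("chr1", 4951, "50M50S"))$pair_type, "RU")
  # trans green -> walk (masked)
  expect_identical(parse1(base("chr2", 4951, "50M50S"))$pair_type, "WW")
  # same strand as blue -> walk: green on + (flag without 0x10)
  sam_same <- c(sam_line("x", 65, "chr1", 1000, 60, "50M50S"),
                sam_line("x", 2113, "chr1", 4951, 60, "50S50M"),
                sam_line("x", 129, "chr1", 4900, 60, "100M"))
  expect_identical(parse1(sam_same)$pair_type, "WW")
  # too far -> walk
  expect_identical(parse1(base("chr1", 8000, "50M50S"))$pair_type, "WW")
})

test_that("chains insert null segments only for gaps beyond the tolerance", {
  cfg <- parse_config()
  aln <- parse_sam_alignments(c(
    sam_line("r", 65, "chr1", 1000, 60, "40M60S"),
    sam_line("r", 2113, "chr1", 2000, 60, "40S40M20S")
  ))
  chain <- build_side_chain(aln, cfg)  # spans [0,40) and [40,80): contiguous
  expect_identical(nrow(chain), 2L)
  expect_false(any(chain$null))

  aln2 <- parse_sam_alignments(c(
    sam_line("r", 65, "chr1", 1000, 60, "40M60S"),
    sam_line("r", 2113, "chr1", 2000, 60, "70S30M")
  ))
  chain2 <- build_side_chain(aln2, cfg)  # gap of 30 > 20
  expect_identical(nrow(chain2), 3L)
  expect_true(chain2$null[2])

  unmapped <- parse_sam_alignments(sam_line("r", 69, "*", 0, 0, "*"))
  expect_true(build_side_chain(unmapped, cfg)$null)
})

test_that("overlapping read spans keep the higher-mapq alignment", {
  cfg <- parse_config()
  aln <- parse_sam_alignments(c(
    sam_line("r", 65, "chr1", 1000, 10, "60M40S"),
    sam_line("r", 2113, "chr1", 5000, 60, "30S70M")
  ))
  chain <- build_side_chain(aln, cfg)
  # the low-mapq alignment is dropped; its read span becomes a leading
  # unaligned gap, recorded as a null segment
  expect_identical(sum(!chain$null), 1L)
  expect_identical(chain[null == FALSE]$ref_start, 5000L)
})

test_that("full readthrough of a single fragment collapses to one segment", {
  cfg <- parse_config()
  c1 <- build_side_chain(parse_sam_alignments(c(
    sam_line("r", 65, "chr1", 1000, 60, "50M50S"),
    sam_line("r", 2113, "chr1", 3000, 60, "50S50M")
  )), cfg)
  c2 <- build_side_chain(parse_sam_alignments(c(
    sam_line("r", 145, "chr1", 3000, 60, "50S50M"),
    sam_line("r", 2193, "chr1", 1000, 60, "50M50S")
  )), cfg)
  merged <- collapse_readthrough(c1, c2, cfg)
  expect_identical(nrow(merged), 2L)  # two fragments, one junction
  # non-overlapping sides stay unmerged
  c3 <- build_side_chain(parse_sam_alignments(
    sam_line("r", 145, "chr1", 8000, 60, "100M")), cfg)
  expect_identical(nrow(collapse_readthrough(c1, c3, cfg)), 3L)
})

test_that("pair types order the lesser mapping class first", {
  expect_identical(assign_pair_type("U", "N", flip = TRUE), "NU")
  expect_identical(assign_pair_type("U", "M", flip = TRUE), "MU")
  expect_identical(assign_pair_type("N", "U", flip = TRUE), "NU")
  expect_identical(assign_pair_type("U", "U", flip = TRUE), "UU")
})

test_that("parse recovers simulator truth on a clean library", {
  cfg <- sim_config(seed = 11, chromosomes = c(chr1 = 400000L,
                                               chr2 = 400000L),
                    n_molecules = 1000, duplication_rate = 0,
                    walk_fraction = 0,
                    byproduct_rates = c(dangling_end = 0, self_circle = 0,
                                        mirror = 0))
  lib <- simulate_library(cfg)
  res <- parse_pairs(lib$sam, lib$genome$chromsizes, parse_config())
  expect_identical(nrow(res$pairs), 1000L)
  expect_gte(mean(pair_coord_key(res$pairs) %in%
                    pair_coord_key(lib$truth)), 0.99)
})

test_that("flipped parse output is invariant under a second flip", {
  cfg <- sim_config(seed = 3, n_molecules = 500, walk_fraction = 0.1)
  lib <- simulate_library(cfg)
  res <- parse_pairs(lib$sam, lib$genome$chromsizes, parse_config())
  expect_equal(flip_pairs(res$pairs, lib$genome$chromsizes), res$pairs)
})

test_that("extra columns are emitted on request", {
  sc <- s1_scenarios()$a
  res <- parse_pairs(c(sam_header_lines(), sc$sam), fix_chromsizes,
                     parse_config(extra_columns = c("mapq1", "mapq2")))
  expect_identical(res$pairs$mapq1, 60L)
  expect_identical(res$pairs$mapq2, 60L)
  expect_identical(res$header$columns,
                   c(pairsuite:::.PAIRS_CORE_COLUMNS, "mapq1", "mapq2"))
})
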