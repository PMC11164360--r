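test_that("digestion places boundaries at position 1 and at site matches", {
  fm <- digest_genome(c(chrT = "AAGATCAA"), "GATC")
  expect_identical(fm$starts$chrT, c(1L, 3L))
  expect_identical(unname(fm$lengths["chrT"]), 8L)

  # no match: a single fragment spans the chromosome
  fm2 <- digest_genome(c(chrT = "AAAAAAAA"), "GATC")
  expect_identical(fm2$starts$chrT, 1L)
})

test_that("non-palindromic sites are matched on both strands, once each", {
  # GGTCTC (BsaI-like): reverse complement GAGACC
  seq <- paste0("AAAA", "GGTCTC", "AAAA", "GAGACC", "AAAA")
  fm <- digest_genome(c(chrT = seq), "GGTCTC")
  expect_identical(fm$starts$chrT, c(1L, 5L, 15L))
})

test_that("IUPAC ambiguity codes are honoured", {
  # GANTC matches GAATC and GATTC
  fm <- digest_genome(c(chrT = "TTGAATCTTGATTCTT"), "GANTC")
  expect_identical(fm$starts$chrT, c(1L, 3L, 10L))
  expect_error(digest_genome(c(chrT = "ACGT"), "GAXC"), "non-IUPAC")
})

test_that("random digests equal the naive sliding-window oracle", {
  set.seed(7)
  for (site in c("GATC", "GANTC")) {
    seq <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE),
                 collapse = "")
    fm <- digest_genome(c(chrR = seq), site)
    expect_identical(fm$starts$chrR, oracle_digest(seq, site))
  }
})

test_that("annotation finds the enclosing fragment by binary search", {
  fm <- digest_genome(c(chrT = "AAGATCAA"), "GATC")
  dt <- data.table::data.table(
    readID = c("a", "b"), chrom1 = "chrT", pos1 = c(5L, 1L),
    chrom2 = "chrT", pos2 = c(2L, 8L), strand1 = "+", strand2 = "-",
    pair_type = "UU"
  )
  ann <- annotate_restriction(dt, fm)
  expect_identical(ann$rfrag1, c(1L, 0L))
  expect_identical(ann$rfrag_start1, c(3L, 1L))
  expect_identical(ann$rfrag_end1, c(9L, 3L))
  expect_identical(ann$rfrag2, c(0L, 1L))

  # null sides annotated with the sentinel
  dt_null <- data.table::data.table(
    readID = "n", chrom1 = "!", pos1 = 0L, chrom2 = "chrT", pos2 = 4L,
    strand1 = ".", strand2 = "+", pair_type = "NU"
  )
  expect_identical(annotate_restriction(dt_null, fm)$rfrag1, -1L)
  # beyond chromosome end
  dt_bad <- data.table::copy(dt)[1, pos1 := 99L]
  expect_error(annotate_restriction(dt_bad, fm), "beyond")
})

test_that("random annotations equal a linear scan", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = "")
  fm <- digest_genome(c(chrR = seq), "GATC")
  n <- 10000
  dt <- data.table::data.table(
    readID = sprintf("r%d", seq_len(n)),
    chrom1 = "chrR", pos1 = sample.int(100000, n, TRUE),
    chrom2 = "chrR", pos2 = sample.int(100000, n, TRUE),
    strand1 = "+", strand2 = "-", pair_type = "UU"
  )
  ann <- annotate_restriction(dt, fm)
  starts <- fm$starts$chrR
  linear_idx <- vapply(dt$pos1, function(p) sum(starts <= p) - 1L,
                       integer(1))
  expect_identical(ann$rfrag1, linear_idx)
})

test_that("by-products partition same-fragment pairs by orientation", {
  fm <- digest_genome(c(chrT = paste(rep("A", 100), collapse = "")),
                      "GATC")  # single fragment
  mk <- function(s1, s2) data.table::data.table(
    readID = "x", chrom1 = "chrT", pos1 = 10L, chrom2 = "chrT",
    pos2 = 60L, strand1 = s1, strand2 = s2, pair_type = "UU"
  )
  expect_identical(classify_byproduct(annotate_restriction(mk("+", "-"),
                                                           fm)),
                   "dangling_end")
  expect_identical(classify_byproduct(annotate_restriction(mk("-", "+"),
                                                           fm)),
                   "self_circle")
  expect_identical(classify_byproduct(annotate_restriction(mk("+", "+"),
                                                           fm)),
                   "mirror")
  expect_identical(classify_byproduct(annotate_restriction(mk("-", "-"),
                                                           fm)),
                   "mirror")
  expect_error(classify_byproduct(mk("+", "-")), "annotate_restriction")
})

test_that("pairs on different fragments are valid ligation products", {
  fm <- digest_genome(c(chrT = "AAGATCAAAAGATCAA"), "GATC")
  dt <- data.table::data.table(
    readID = "x", chrom1 = "chrT", pos1 = 4L, chrom2 = "chrT",
    pos2 = 12L, strand1 = "+", strand2 = "-", pair_type = "UU"
  )
  expect_identical(classify_byproduct(annotate_restriction(dt, fm)),
                   "valid")
})

test_that("simulated by-products classify exactly as planted", {
  cfg <- sim_config(seed = 19, chromosomes = c(chr1 = 300000L),
                    n_molecules = 600, duplication_rate = 0,
                    walk_fraction = 0,
                    byproduct_rates = c(dangling_end = 0.3,
                                        self_circle = 0.3, mirror = 0.3),
                    restriction_site = "GATC")
  lib <- simulate_library(cfg)
  res <- parse_pairs(lib$sam, lib$genome$chromsizes, parse_config())
  fm <- digest_genome(lib$genome$sequences, "GATC")
  ann <- annotate_restriction(res$pairs, fm)
  got <- classify_byproduct(ann)
  planted <- lib$truth[match(res$pairs$readID, lib$truth$readID)]$class
  bp <- planted %in% c("dangling_end", "self_circle", "mirror")
  expect_identical(got[bp], planted[bp])
})

test_that("fragment maps round-trip through the BED3 serialization", {
  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  fm <- digest_genome(c(chrR = seq, chrS = substr(seq, 1, 2000)), "GATC")
  path <- withr::local_tempfile(fileext = ".bed")
  write_fragments(fm, path)
  back <- read_fragments(path)
  expect_identical(back$starts[names(fm$starts)], fm$starts)
  expect_identical(back$lengths[names(fm$lengths)], fm$lengths)
})
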