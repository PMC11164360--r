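# Shared fixtures and independent oracles, built in code.

library(data.table)

# ---- generic .pairs fixtures ------------------------------------------------

fix_chromsizes <- c(chr1 = 10000L, chr2 = 10000L, chr3 = 10000L)

fix_header <- function(columns = c("readID", "chrom1", "pos1", "chrom2",
                                   "pos2", "strand1", "strand2",
                                   "pair_type"),
                       chromsizes = fix_chromsizes) {
  pairs_header(chromsizes, columns = columns)
}

# random flipped UU records on a small genome
random_pairs <- function(n, chromsizes = fix_chromsizes, seed = 1L) {
  set.seed(seed)
  chroms <- names(chromsizes)
  dt <- data.table(
    readID = sprintf("r%06d", seq_len(n)),
    chrom1 = sample(chroms, n, TRUE),
    pos1 = sample.int(min(chromsizes), n, TRUE),
    chrom2 = sample(chroms, n, TRUE),
    pos2 = sample.int(min(chromsizes), n, TRUE),
    strand1 = sample(c("+", "-"), n, TRUE),
    strand2 = sample(c("+", "-"), n, TRUE),
    pair_type = "UU"
  )
  flip_pairs(dt, chromsizes)
}

# ---- SAM fixtures -----------------------------------------------------------

sam_line <- function(qname, flag, rname, pos, mapq, cigar, tags = NULL) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*", tags),
        collapse = "\t")
}

sam_header_lines <- function(chromsizes = fix_chromsizes) {
  c("@HD\tVN:1.6\tGO:query",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chromsizes), chromsizes))
}

# The eight canonical chimeric-read scenarios (one read pair each), with the
# outputs each walk policy must produce.  Coordinates are the 5' ends of the
# chosen alignments; records are given flipped.
s1_scenarios <- function() {
  list(
    a = list(
      sam = c(sam_line("a", 65, "chr1", 1000, 60, "100M"),
              sam_line("a", 145, "chr2", 2000, 60, "100M")),
      expect = list(all_policies = data.table(
        chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
        chrom2 = "chr2", pos2 = 2099L, strand2 = "-", pair_type = "UU"))
    ),
    b_one_sided = list(
      sam = c(sam_line("b1", 69, "*", 0, 0, "*"),
              sam_line("b1", 145, "chr1", 3000, 60, "100M")),
      expect = list(all_policies = data.table(
        chrom1 = "!", pos1 = 0L, strand1 = ".",
        chrom2 = "chr1", pos2 = 3099L, strand2 = "-", pair_type = "NU"))
    ),
    b_both = list(
      sam = c(sam_line("b2", 69, "*", 0, 0, "*"),
              sam_line("b2", 133, "*", 0, 0, "*")),
      expect = list(all_policies = data.table(
        chrom1 = "!", pos1 = 0L, strand1 = ".",
        chrom2 = "!", pos2 = 0L, strand2 = ".", pair_type = "NN"))
    ),
    c_multi = list(
      sam = c(sam_line("c", 65, "chr1", 1000, 0, "100M"),
              sam_line("c", 145, "chr2", 2000, 60, "100M")),
      expect = list(all_policies = data.table(
        chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
        chrom2 = "chr2", pos2 = 2099L, strand2 = "-", pair_type = "MU"))
    ),
    d_rescue = list(
      sam = c(sam_line("d", 65, "chr1", 1000, 60, "50M50S"),
              sam_line("d", 2129, "chr1", 4951, 60, "50M50S"),
              sam_line("d", 129, "chr1", 4900, 60, "100M")),
      expect = list(all_policies = data.table(
        chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
        chrom2 = "chr1", pos2 = 4900L, strand2 = "+", pair_type = "RU"))
    ),
    e_walk = list(
      sam = c(sam_line("e", 65, "chr1", 1000, 60, "50M50S"),
              sam_line("e", 2129, "chr2", 4951, 60, "50M50S"),
              sam_line("e", 129, "chr1", 4900, 60, "100M")),
      expect = list(
        mask = data.table(
          chrom1 = "!", pos1 = 0L, strand1 = ".",
          chrom2 = "!", pos2 = 0L, strand2 = ".", pair_type = "WW"),
        all = data.table(
          chrom1 = c("chr1", "chr1"), pos1 = c(1000L, 4900L),
          strand1 = c("+", "+"),
          chrom2 = c("chr2", "chr2"), pos2 = c(4951L, 5000L),
          strand2 = c("+", "-"), pair_type = c("UU", "UU")),
        `5unique` = data.table(
          chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
          chrom2 = "chr1", pos2 = 4900L, strand2 = "+", pair_type = "UU"),
        `5any` = data.table(
          chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
          chrom2 = "chr1", pos2 = 4900L, strand2 = "+", pair_type = "UU"),
        `3unique` = data.table(
          chrom1 = "chr1", pos1 = 4900L, strand1 = "+",
          chrom2 = "chr2", pos2 = 5000L, strand2 = "-", pair_type = "UU"),
        `3any` = data.table(
          chrom1 = "chr1", pos1 = 4900L, strand1 = "+",
          chrom2 = "chr2", pos2 = 5000L, strand2 = "-", pair_type = "UU"))
    ),
    f_three_ligations = list(
      sam = c(sam_line("f", 65, "chr1", 1000, 60, "50M50S"),
              sam_line("f", 2113, "chr1", 3000, 60, "50S50M"),
              sam_line("f", 129, "chr2", 2000, 60, "50M50S"),
              sam_line("f", 2177, "chr1", 5000, 60, "50S50M")),
      expect = list(
        mask = data.table(
          chrom1 = "!", pos1 = 0L, strand1 = ".",
          chrom2 = "!", pos2 = 0L, strand2 = ".", pair_type = "WW"),
        all = data.table(
          chrom1 = c("chr1", "chr1", "chr1"),
          pos1 = c(1000L, 3000L, 5049L),
          strand1 = c("+", "+", "-"),
          chrom2 = c("chr1", "chr1", "chr2"),
          pos2 = c(3049L, 5000L, 2000L),
          strand2 = c("-", "+", "+"),
          pair_type = c("UU", "UU", "UU")),
        `5unique` = data.table(
          chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
          chrom2 = "chr2", pos2 = 2000L, strand2 = "+", pair_type = "UU"),
        `5any` = data.table(
          chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
          chrom2 = "chr2", pos2 = 2000L, strand2 = "+", pair_type = "UU"),
        `3unique` = data.table(
          chrom1 = "chr1", pos1 = 3000L, strand1 = "+",
          chrom2 = "chr1", pos2 = 5000L, strand2 = "+", pair_type = "UU"),
        `3any` = data.table(
          chrom1 = "chr1", pos1 = 3000L, strand1 = "+",
          chrom2 = "chr1", pos2 = 5000L, strand2 = "+", pair_type = "UU"))
    ),
    g_readthrough = list(
      sam = c(sam_line("g", 65, "chr1", 1000, 60, "50M100S"),
              sam_line("g", 2113, "chr1", 3000, 60, "50S50M50S"),
              sam_line("g", 2113, "chr1", 5000, 60, "100S50M"),
              sam_line("g", 145, "chr1", 7000, 60, "100S50M"),
              sam_line("g", 2193, "chr1", 5000, 60, "50S50M50S"),
              sam_line("g", 2193, "chr1", 3000, 60, "50M100S")),
      expect = list(
        all = data.table(
          chrom1 = c("chr1", "chr1", "chr1"),
          pos1 = c(1000L, 3000L, 5000L),
          strand1 = c("+", "+", "+"),
          chrom2 = c("chr1", "chr1", "chr1"),
          pos2 = c(3049L, 5049L, 7049L),
          strand2 = c("-", "-", "-"),
          pair_type = c("UU", "UU", "UU")),
        mask = data.table(
          chrom1 = "!", pos1 = 0L, strand1 = ".",
          chrom2 = "!", pos2 = 0L, strand2 = ".", pair_type = "WW"),
        `5unique` = data.table(
          chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
          chrom2 = "chr1", pos2 = 7049L, strand2 = "-", pair_type = "UU"))
    ),
    h_unmapped_5p = list(
      sam = c(sam_line("h", 65, "chr1", 5000, 60, "50S50M"),
              sam_line("h", 145, "chr2", 3000, 60, "100M")),
      expect = list(
        `5any` = data.table(
          chrom1 = "!", pos1 = 0L, strand1 = ".",
          chrom2 = "chr2", pos2 = 3099L, strand2 = "-", pair_type = "NU"),
        `5unique` = data.table(
          chrom1 = "chr1", pos1 = 5000L, strand1 = "+",
          chrom2 = "chr2", pos2 = 3099L, strand2 = "-", pair_type = "UU"),
        mask = data.table(
          chrom1 = "!", pos1 = 0L, strand1 = ".",
          chrom2 = "!", pos2 = 0L, strand2 = ".", pair_type = "WW"))
    )
  )
}

s1_parse <- function(scenario, policy) {
  res <- parse_pairs(c(sam_header_lines(), scenario$sam), fix_chromsizes,
                     parse_config(walk_policy = policy))
  res$pairs[, intersect(c("chrom1", "pos1", "strand1", "chrom2", "pos2",
                          "strand2", "pair_type"), names(res$pairs)),
            with = FALSE][
    , .(chrom1, pos1, strand1, chrom2, pos2, strand2, pair_type)]
}

# ---- independent oracles ----------------------------------------------------

# naive CIGAR interpreter, character by character
oracle_cigar <- function(cigar) {
  ref <- 0L; qaln <- 0L; lead <- 0L; trail <- 0L
  num <- 0L; seen_aligned <- FALSE; pending_clip <- 0L
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) {
      num <- num * 10L + as.integer(ch)
    } else {
      if (ch %in% c("M", "D", "N", "=", "X")) ref <- ref + num
      if (ch %in% c("M", "I", "=", "X")) qaln <- qaln + num
      if (ch %in% c("S", "H")) {
        if (!seen_aligned) lead <- lead + num else trail <- trail + num
      } else {
        seen_aligned <- TRUE
      }
      num <- 0L
    }
  }
  list(ref_len = ref, query_aln = qaln, lead = lead, trail = trail)
}

# brute-force all-pairs duplicate clustering: full adjacency matrix plus a
# hand-rolled union-find for the transitive closure
oracle_dedup_clusters <- function(pairs, max_mismatch,
                                  match_extras = NULL) {
  n <- nrow(pairs)
  key <- do.call(paste, c(list(pairs$chrom1, pairs$chrom2, pairs$strand1,
                               pairs$strand2),
                          lapply(match_extras, function(cn) pairs[[cn]])))
  adj <- outer(key, key, "==") &
    abs(outer(pairs$pos1, pairs$pos1, "-")) <= max_mismatch &
    abs(outer(pairs$pos2, pairs$pos2, "-")) <= max_mismatch
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1])
    rj <- find(edges[e, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# sorted random dedup instance on a small genome
random_dedup_instance <- function(n, genome_size = 10000L, seed = 1L,
                                  chromsizes = c(chrZ = 10000L)) {
  set.seed(seed)
  dt <- data.table(
    readID = sprintf("d%05d", seq_len(n)),
    chrom1 = "chrZ",
    pos1 = sample.int(genome_size, n, TRUE),
    chrom2 = "chrZ",
    pos2 = sample.int(genome_size, n, TRUE),
    strand1 = sample(c("+", "-"), n, TRUE),
    strand2 = sample(c("+", "-"), n, TRUE),
    pair_type = "UU"
  )
  sort_pairs(flip_pairs(dt, chromsizes), chromsizes)
}

# naive restriction digest by sliding-window comparison with IUPAC codes
oracle_digest <- function(seq, site) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  match_at <- function(chars, site_chars, p) {
    all(mapply(function(sc, c) c %in% iupac[[sc]],
               site_chars, chars[p:(p + length(site_chars) - 1L)]))
  }
  chars <- strsplit(seq, "")[[1]]
  hits <- integer()
  for (s in unique(c(site, revcomp(site)))) {
    sc <- strsplit(s, "")[[1]]
    for (p in seq_len(length(chars) - length(sc) + 1L)) {
      if (match_at(chars, sc, p)) hits <- c(hits, p)
    }
  }
  sort(unique(c(1L, hits)))
}

# planted-convergence cis pairs: below s_star the orientation mix is skewed
# (dangling-end-like +- excess), above it all orientations are equal
planted_convergence_pairs <- function(n, s_star = 2000, seed = 1L,
                                      chrom_len = 2e6L,
                                      s_min = 100, s_max = 1e6) {
  set.seed(seed)
  s <- round(exp(runif(n, log(s_min), log(s_max))))
  orient <- character(n)
  below <- s < s_star
  opts <- c("++", "+-", "-+", "--")
  orient[below] <- sample(opts, sum(below), TRUE,
                          prob = c(0.1, 0.7, 0.1, 0.1))
  orient[!below] <- sample(opts, sum(!below), TRUE)
  pos1 <- floor(runif(n, 1, chrom_len - s))
  data.table(
    readID = sprintf("p%07d", seq_len(n)),
    chrom1 = "chrA", pos1 = as.integer(pos1),
    chrom2 = "chrA", pos2 = as.integer(pos1 + s),
    strand1 = substr(orient, 1, 1), strand2 = substr(orient, 2, 2),
    pair_type = "UU"
  )
}

# expected surviving records after perfect dedup of a simulated library:
# per duplicate group, the copy that sorts first on true coordinates
truth_expected_unique <- function(truth, chromsizes) {
  key <- truth[, .(dup_group, r1 = match(chrom1, names(chromsizes)),
                   r2 = match(chrom2, names(chromsizes)),
                   pos1, pos2, strand1, strand2, readID,
                   row = seq_len(nrow(truth)))]
  setorder(key, r1, r2, pos1, pos2, strand1, strand2)
  first <- key[!duplicated(dup_group)]
  truth[first$row]
}

pair_coord_key <- function(dt) {
  paste(dt$chrom1, dt$pos1, dt$strand1, dt$chrom2, dt$pos2, dt$strand2)
}
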