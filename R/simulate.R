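#' Simulation configuration for synthetic 3C+ libraries
#'
#' Describes a synthetic proximity-ligation experiment with known ground
#' truth: a random (optionally diploid) genome, chimeric molecules composed
#' of 2-4 ligated fragments, paired-end reads written as a perfect local
#' aligner would report them (split segments as supplementary records,
#' soft-clipped CIGARs, mates aligned independently), PCR duplicates with
#' 1 bp coordinate jitter, and the classic restriction by-products.
#'
#' Defaults emulate a reasonably deep conventional Hi-C library: mostly
#' single-ligation molecules with a cis fraction of 0.7, cis separations
#' decaying as a power law `P(s) ~ s^-1`, 100 bp paired-end reads of
#' ~250 bp sonicated molecules, a modest duplication rate, a few percent of
#' multi-junction walks and about 1-2 % ligation by-products.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param chromosomes Named integer vector of chromosome lengths.
#' @param n_molecules Number of distinct molecules (pre-PCR pool).
#' @param cis_fraction Probability that a ligation joins loci of one
#'   chromosome.
#' @param scaling_exponent Power-law slope of cis separations
#'   (`P(s) ~ s^-exponent`).
#' @param min_separation Smallest cis separation drawn (bp).
#' @param read_length Read length (bp) of both mates.
#' @param fragment_length `c(mean=, sd=)` of ligated fragment lengths (bp),
#'   truncated to [50, 2000].
#' @param walk_fragment_length `c(min=, max=)` of fragment lengths in
#'   multi-junction walks; short enough that reads span the junctions.
#' @param duplication_rate Expected number of extra PCR copies per molecule
#'   (Poisson).
#' @param walk_fraction Fraction of molecules with 2-3 ligation junctions.
#' @param byproduct_rates `c(dangling_end=, self_circle=, mirror=)`
#'   fractions.
#' @param diploid Simulate two haplotype copies of each chromosome
#'   (names `chr<sep>0` / `chr<sep>1`) and emit suboptimal-alignment XB
#'   tags for phasing.
#' @param snv_rate Per-bp heterozygosity between the two haplotypes.
#' @param restriction_site Optional IUPAC recognition site; when set,
#'   by-product fragments coincide with restriction fragments of the
#'   simulated genome.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = c(chrA = 1000000L, chrB = 1000000L),
                       n_molecules = 10000L,
                       cis_fraction = 0.7,
                       scaling_exponent = 1.0,
                       min_separation = 500L,
                       read_length = 100L,
                       fragment_length = c(mean = 250, sd = 50),
                       walk_fragment_length = c(min = 40, max = 70),
                       duplication_rate = 0.1,
                       walk_fraction = 0.02,
                       byproduct_rates = c(dangling_end = 0.01,
                                           self_circle = 0.005,
                                           mirror = 0.002),
                       diploid = FALSE,
                       snv_rate = 0.001,
                       restriction_site = NULL) {
  stopifnot(
    all(chromosomes > 0L), n_molecules >= 1L,
    cis_fraction >= 0, cis_fraction <= 1,
    walk_fraction >= 0, all(byproduct_rates >= 0),
    walk_fraction + sum(byproduct_rates) <= 1,
    read_length >= 20L, min_separation >= 1L,
    snv_rate >= 0, snv_rate <= 1
  )
  structure(
    list(seed = as.integer(seed), chromosomes = .as_chromsizes(chromosomes),
         n_molecules = as.integer(n_molecules),
         cis_fraction = cis_fraction,
         scaling_exponent = scaling_exponent,
         min_separation = as.integer(min_separation),
         read_length = as.integer(read_length),
         fragment_length = fragment_length,
         walk_fragment_length = walk_fragment_length,
         duplication_rate = duplication_rate,
         walk_fraction = walk_fraction,
         byproduct_rates = byproduct_rates,
         diploid = isTRUE(diploid), snv_rate = snv_rate,
         restriction_site = restriction_site),
    class = "sim_config"
  )
}

.SIM_BASES <- c("A", "C", "G", "T")

#' Simulate a random (optionally diploid) genome
#'
#' Uniform-random nucleotide sequences, deterministic per seed.  In diploid
#' mode each chromosome is emitted as two haplotype copies named
#' `<name>#0` / `<name>#1`, the second differing from the first at
#' Bernoulli(`snv_rate`) positions; planted variants are recorded.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character vector), `chromsizes`
#'   (named integer vector in canonical order), `variants` (`data.table`
#'   chrom/pos/ref/alt on base names) and `config`.
#' @export
simulate_genome <- function(config) {
  .with_seed(config$seed, {
    base_seqs <- vapply(config$chromosomes, function(len) {
      paste(sample(.SIM_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
    if (!config$diploid) {
      return(list(sequences = base_seqs,
                  chromsizes = config$chromosomes,
                  variants = data.table::data.table(
                    chrom = character(), pos = integer(),
                    ref = character(), alt = character()),
                  config = config))
    }
    seqs <- character()
    var_list <- list()
    for (nm in names(base_seqs)) {
      len <- config$chromosomes[[nm]]
      vpos <- which(runif(len) < config$snv_rate)
      hap1 <- base_seqs[[nm]]
      if (length(vpos)) {
        ref <- substring(hap1, vpos, vpos)
        alt <- vapply(ref, function(r) sample(setdiff(.SIM_BASES, r), 1L),
                      character(1), USE.NAMES = FALSE)
        hap1_chars <- strsplit(hap1, "", fixed = TRUE)[[1]]
        hap1_chars[vpos] <- alt
        hap1 <- paste(hap1_chars, collapse = "")
        var_list[[nm]] <- data.table::data.table(
          chrom = nm, pos = vpos, ref = ref, alt = alt)
      }
      seqs[[paste0(nm, "#0")]] <- base_seqs[[nm]]
      seqs[[paste0(nm, "#1")]] <- hap1
    }
    list(
      sequences = seqs,
      chromsizes = stats::setNames(
        rep(config$chromosomes, each = 2L),
        paste0(rep(names(config$chromosomes), each = 2L), "#", 0:1)),
      variants = if (length(var_list)) data.table::rbindlist(var_list)
      else data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()),
      config = config
    )
  })
}

# power-law separation draw: density ~ s^-alpha on [smin, smax]
.draw_separation <- function(n, alpha, smin, smax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-9) {
    as.integer(round(exp(log(smin) + u * (log(smax) - log(smin)))))
  } else {
    a1 <- 1 - alpha
    as.integer(round((u * (smax^a1 - smin^a1) + smin^a1)^(1 / a1)))
  }
}

# uniform integer start so that [start, start + len - 1] fits in [1, size]
.draw_start <- function(size, len) {
  as.integer(floor(runif(length(len)) * (size - len + 1))) + 1L
}

# alignment of the read-1 portion [qs, qe) of a fragment (chrom, af..bf,
# strand g) whose molecule offset is `of`; rlen = read length
.map_read1 <- function(chrom, af, bf, g, of, qs, qe, rlen) {
  fwd <- g == "+"
  data.table::data.table(
    side = 1L, chrom = chrom,
    sam_strand = data.table::fifelse(fwd, "+", "-"),
    ref_start = as.integer(data.table::fifelse(fwd, af + (qs - of),
                                               bf - (qe - of) + 1L)),
    ref_end = as.integer(data.table::fifelse(fwd, af + (qe - of) - 1L,
                                             bf - (qs - of))),
    lead = as.integer(data.table::fifelse(fwd, qs, rlen - qe)),
    mid = as.integer(qe - qs),
    trail = as.integer(data.table::fifelse(fwd, rlen - qe, qs)),
    read_start = as.integer(qs), as_score = as.integer(qe - qs)
  )
}

# alignment of the read-2 portion: molecule coords [ms, me), molecule
# length L; read 2 is the reverse complement of the molecule 3' end
.map_read2 <- function(chrom, af, bf, g, of, ms, me, L, rlen) {
  fwd <- g == "+"
  rs <- L - me
  re <- L - ms
  data.table::data.table(
    side = 2L, chrom = chrom,
    sam_strand = data.table::fifelse(fwd, "-", "+"),
    ref_start = as.integer(data.table::fifelse(fwd, af + (ms - of),
                                               bf - (me - of) + 1L)),
    ref_end = as.integer(data.table::fifelse(fwd, af + (me - of) - 1L,
                                             bf - (ms - of))),
    lead = as.integer(data.table::fifelse(fwd, rlen - re, rs)),
    mid = as.integer(me - ms),
    trail = as.integer(data.table::fifelse(fwd, rs, rlen - re)),
    read_start = as.integer(rs), as_score = as.integer(me - ms)
  )
}

.sim_cigar <- function(lead, mid, trail) {
  paste0(data.table::fifelse(lead > 0L, paste0(lead, "S"), ""),
         mid, "M",
         data.table::fifelse(trail > 0L, paste0(trail, "S"), ""))
}

#' Simulate a 3C+ sequencing library with ground truth
#'
#' Draws molecules according to the configured class rates, writes their
#' paired-end alignments as SAM text (name-grouped, split segments as
#' supplementary records, mates aligned independently) and returns a truth
#' table with one row per emitted read pair: the expected contact under the
#' `5unique` reporting convention (5'-most unique segment of each side,
#' coordinate jitter of PCR copies included), the duplicate group, the
#' molecule class, and for diploid genomes the haplotype and whether each
#' side covers a planted variant.
#'
#' @param config A [sim_config()].
#' @param genome A [simulate_genome()] result for `config`.
#' @return List with `truth` (`data.table`), `sam` (character vector of SAM
#'   lines incl. header), `genome` and `config`.
#' @export
simulate_library <- function(config, genome = simulate_genome(config)) {
  .with_seed(config$seed + 1L, {
    .simulate_library_impl(config, genome)
  })
}

.simulate_library_impl <- function(config, genome) {
  n <- config$n_molecules
  rl <- config$read_length
  br <- config$byproduct_rates
  p_classes <- c(
    contact = 1 - config$walk_fraction - sum(br),
    walk = config$walk_fraction,
    dangling_end = unname(br["dangling_end"]),
    self_circle = unname(br["self_circle"]),
    mirror = unname(br["mirror"])
  )
  cls <- sample(names(p_classes), n, replace = TRUE, prob = p_classes)
  base_names <- names(config$chromosomes)
  base_lens <- unname(config$chromosomes)
  mol_hap <- if (config$diploid) sample(0:1, n, replace = TRUE) else
    rep(NA_integer_, n)
  chrom_of <- function(base_idx, h) {
    if (config$diploid) paste0(base_names[base_idx], "#", h)
    else base_names[base_idx]
  }

  rfrag_tab <- NULL
  if (!is.null(config$restriction_site)) {
    rmap <- digest_genome(genome$sequences, config$restriction_site)
    rfrag_tab <- data.table::rbindlist(lapply(names(rmap$starts), function(ch) {
      st <- rmap$starts[[ch]]
      en <- c(st[-1] - 1L, rmap$lengths[[ch]])
      data.table::data.table(chrom = ch, start = st, end = en,
                             len = en - st + 1L)
    }))
  }

  templates <- list()   # alignment template rows, col `mol` set
  truth_mol <- list()   # per-molecule truth (side views, unjittered)

  # ---- single-ligation contacts (vectorised) ------------------------------
  idx <- which(cls == "contact")
  if (length(idx)) {
    m <- length(idx)
    fl <- config$fragment_length
    L1 <- as.integer(pmin(pmax(round(rnorm(m, fl[["mean"]], fl[["sd"]])),
                               50), 2000))
    L2 <- as.integer(pmin(pmax(round(rnorm(m, fl[["mean"]], fl[["sd"]])),
                               50), 2000))
    ci1 <- sample(seq_along(base_names), m, replace = TRUE,
                  prob = base_lens)
    a1 <- .draw_start(base_lens[ci1], L1)
    is_cis <- runif(m) < config$cis_fraction | length(base_names) == 1L
    ci2 <- ci1
    if (any(!is_cis)) {
      ci2[!is_cis] <- vapply(ci1[!is_cis], function(i) {
        sample(setdiff(seq_along(base_names), i), 1L)
      }, integer(1))
    }
    a2 <- integer(m)
    if (any(!is_cis)) {
      a2[!is_cis] <- .draw_start(base_lens[ci2[!is_cis]], L2[!is_cis])
    }
    if (any(is_cis)) {
      k <- sum(is_cis)
      smax <- pmax(base_lens[ci1[is_cis]] %/% 2L,
                   config$min_separation + 1L)
      s <- .draw_separation(k, config$scaling_exponent,
                            config$min_separation, smax)
      dir <- sample(c(-1L, 1L), k, replace = TRUE)
      cand <- a1[is_cis] + dir * s
      hi <- base_lens[ci1[is_cis]] - L2[is_cis] + 1L
      out <- cand < 1L | cand > hi
      cand[out] <- a1[is_cis][out] - dir[out] * s[out]
      a2[is_cis] <- as.integer(pmin(pmax(cand, 1L), hi))
    }
    g1 <- sample(c("+", "-"), m, replace = TRUE)
    g2 <- sample(c("+", "-"), m, replace = TRUE)
    b1 <- a1 + L1 - 1L
    b2 <- a2 + L2 - 1L
    ch1 <- chrom_of(ci1, mol_hap[idx])
    ch2 <- chrom_of(ci2, mol_hap[idx])
    L <- L1 + L2
    r1 <- pmin(rl, L)
    r2 <- r1
    rows <- list(
      .map_read1(ch1, a1, b1, g1, 0L, 0L, pmin(r1, L1), r1)[, mol := idx],
      {
        w <- r1 > L1
        .map_read1(ch2[w], a2[w], b2[w], g2[w], L1[w], L1[w], r1[w],
                   r1[w])[, mol := idx[w]]
      },
      .map_read2(ch2, a2, b2, g2, L1, pmax(L - r2, L1), L, L,
                 r2)[, mol := idx],
      {
        w <- (L - r2) < L1
        .map_read2(ch1[w], a1[w], b1[w], g1[w], 0L, (L - r2)[w], L1[w],
                   L[w], r2[w])[, mol := idx[w]]
      }
    )
    templates <- c(templates, rows)
    truth_mol[[length(truth_mol) + 1L]] <- data.table::data.table(
      mol = idx, class = "contact", n_junctions = 1L,
      chrom1 = ch1,
      pos1 = data.table::fifelse(g1 == "+", a1, b1),
      strand1 = g1,
      chrom2 = ch2,
      pos2 = data.table::fifelse(g2 == "+", b2, a2),
      strand2 = .other_strand(g2)
    )
  }

  # ---- restriction by-products (vectorised per class) ---------------------
  pick_interval <- function(m, min_len, want_len) {
    # (chrom index, a, b) of by-product fragments; on restriction maps the
    # fragment IS one restriction fragment
    if (!is.null(rfrag_tab)) {
      ok <- rfrag_tab[len >= min_len]
      if (!nrow(ok)) {
        stop("no restriction fragment long enough (need ", min_len, " bp)")
      }
      j <- sample.int(nrow(ok), m, replace = TRUE)
      list(chrom = ok$chrom[j], a = ok$start[j], b = ok$end[j])
    } else {
      len <- as.integer(pmax(want_len, min_len))
      ci <- sample(seq_along(base_names), m, replace = TRUE, prob = base_lens)
      a <- .draw_start(base_lens[ci], len)
      list(chrom_idx = ci, a = a, b = a + len - 1L)
    }
  }
  resolve_chrom <- function(iv, hapv) {
    if (!is.null(rfrag_tab)) iv$chrom else chrom_of(iv$chrom_idx, hapv)
  }
  for (bp_class in c("dangling_end", "self_circle", "mirror")) {
    idx <- which(cls == bp_class)
    if (!length(idx)) next
    m <- length(idx)
    fl <- config$fragment_length
    want <- as.integer(pmin(pmax(round(rnorm(m, fl[["mean"]], fl[["sd"]])),
                                 50), 2000))
    min_len <- switch(bp_class,
                      dangling_end = 50L,
                      self_circle = 2L * rl + 2L,
                      mirror = rl)
    iv <- pick_interval(m, min_len, want)
    ch <- resolve_chrom(iv, mol_hap[idx])
    a <- iv$a
    b <- iv$b
    if (bp_class == "dangling_end") {
      Lf <- b - a + 1L
      r <- pmin(rl, Lf)
      rows <- list(
        .map_read1(ch, a, b, rep("+", m), 0L, 0L, r, r)[, mol := idx],
        .map_read2(ch, a, b, rep("+", m), 0L, Lf - r, Lf, Lf,
                   r)[, mol := idx]
      )
      t1 <- list(pos1 = a, strand1 = rep("+", m),
                 pos2 = b, strand2 = rep("-", m))
    } else if (bp_class == "self_circle") {
      r <- rl
      rows <- list(
        data.table::data.table(side = 1L, chrom = ch, sam_strand = "-",
                               ref_start = a, ref_end = a + r - 1L,
                               lead = 0L, mid = r, trail = 0L,
                               read_start = 0L, as_score = r, mol = idx),
        data.table::data.table(side = 2L, chrom = ch, sam_strand = "+",
                               ref_start = b - r + 1L, ref_end = b,
                               lead = 0L, mid = r, trail = 0L,
                               read_start = 0L, as_score = r, mol = idx)
      )
      t1 <- list(pos1 = a + r - 1L, strand1 = rep("-", m),
                 pos2 = b - r + 1L, strand2 = rep("+", m))
    } else {  # mirror: both reads on the same position and strand
      r <- rl
      p <- a
      if (!is.null(rfrag_tab)) {
        # anywhere within the fragment that leaves room for the read
        p <- a + as.integer(floor(runif(m) * pmax(b - a + 1L - r, 1L)))
      }
      rows <- lapply(1:2, function(s) {
        data.table::data.table(side = s, chrom = ch, sam_strand = "+",
                               ref_start = p, ref_end = p + r - 1L,
                               lead = 0L, mid = r, trail = 0L,
                               read_start = 0L, as_score = r, mol = idx)
      })
      t1 <- list(pos1 = p, strand1 = rep("+", m),
                 pos2 = p, strand2 = rep("+", m))
    }
    templates <- c(templates, rows)
    truth_mol[[length(truth_mol) + 1L]] <- data.table::data.table(
      mol = idx, class = bp_class, n_junctions = 0L,
      chrom1 = ch, pos1 = t1$pos1, strand1 = t1$strand1,
      chrom2 = ch, pos2 = t1$pos2, strand2 = t1$strand2
    )
  }

  # ---- multi-junction walks (per molecule) --------------------------------
  idx <- which(cls == "walk")
  if (length(idx)) {
    wf <- config$walk_fragment_length
    walk_rows <- vector("list", length(idx))
    walk_truth <- vector("list", length(idx))
    for (w in seq_along(idx)) {
      mol <- idx[w]
      nf <- sample(3:4, 1L)  # 2 or 3 junctions
      lens <- sample(wf[["min"]]:wf[["max"]], nf, replace = TRUE)
      ci <- integer(nf)
      aa <- integer(nf)
      ci[1] <- sample(seq_along(base_names), 1L, prob = base_lens)
      aa[1] <- .draw_start(base_lens[ci[1]], lens[1])
      for (f in 2:nf) {
        if (runif(1) < config$cis_fraction || length(base_names) == 1L) {
          ci[f] <- ci[f - 1L]
          smax <- max(base_lens[ci[f]] %/% 2L, config$min_separation + 1L)
          s <- .draw_separation(1L, config$scaling_exponent,
                                config$min_separation, smax)
          dir <- sample(c(-1L, 1L), 1L)
          cand <- aa[f - 1L] + dir * s
          hi <- base_lens[ci[f]] - lens[f] + 1L
          if (cand < 1L || cand > hi) cand <- aa[f - 1L] - dir * s
          aa[f] <- as.integer(min(max(cand, 1L), hi))
        } else {
          ci[f] <- sample(setdiff(seq_along(base_names), ci[f - 1L]), 1L)
          aa[f] <- .draw_start(base_lens[ci[f]], lens[f])
        }
      }
      gg <- sample(c("+", "-"), nf, replace = TRUE)
      bb <- aa + lens - 1L
      ch <- chrom_of(ci, mol_hap[mol])
      of <- cumsum(c(0L, lens))[seq_len(nf)]
      L <- sum(lens)
      r1 <- min(rl, L)
      r2 <- r1
      rows <- list()
      for (f in seq_len(nf)) {
        qs <- max(0L, of[f])
        qe <- min(r1, of[f] + lens[f])
        if (qe > qs) {
          rows[[length(rows) + 1L]] <-
            .map_read1(ch[f], aa[f], bb[f], gg[f], of[f], qs, qe, r1)
        }
        ms <- max(L - r2, of[f])
        me <- min(L, of[f] + lens[f])
        if (me > ms) {
          rows[[length(rows) + 1L]] <-
            .map_read2(ch[f], aa[f], bb[f], gg[f], of[f], ms, me, L, r2)
        }
      }
      walk_rows[[w]] <- data.table::rbindlist(rows)[, mol := mol]
      walk_truth[[w]] <- data.table::data.table(
        mol = mol, class = "walk", n_junctions = nf - 1L,
        chrom1 = ch[1],
        pos1 = if (gg[1] == "+") aa[1] else bb[1],
        strand1 = gg[1],
        chrom2 = ch[nf],
        pos2 = if (gg[nf] == "+") bb[nf] else aa[nf],
        strand2 = .other_strand(gg[nf])
      )
    }
    templates <- c(templates, walk_rows)
    truth_mol[[length(truth_mol) + 1L]] <-
      data.table::rbindlist(walk_truth)
  }

  templates <- data.table::rbindlist(templates)
  truth_mol <- data.table::rbindlist(truth_mol)
  data.table::setorder(truth_mol, mol)

  # ---- PCR duplication with coordinate jitter -----------------------------
  n_copies <- 1L + rpois(n, config$duplication_rate)
  copies <- data.table::data.table(
    mol = rep(seq_len(n), n_copies),
    copy = unlist(lapply(n_copies, seq_len)) - 1L
  )
  jit <- function(k) sample(c(-1L, 0L, 0L, 1L), k, replace = TRUE)
  copies[, `:=`(d1 = jit(.N), d2 = jit(.N))]
  copies[copy == 0L, `:=`(d1 = 0L, d2 = 0L)]
  copies[, read_id := sprintf("SIM%07d_%d", mol, copy)]

  aln <- templates[copies, on = "mol", allow.cartesian = TRUE]
  aln[, shift := data.table::fifelse(side == 1L, d1, d2)]
  aln[, `:=`(ref_start = pmax(ref_start + shift, 1L),
             ref_end = pmax(ref_end + shift, 1L))]

  # ---- optional phasing tags ----------------------------------------------
  if (config$diploid) {
    sp <- data.table::tstrsplit(aln$chrom, "#", fixed = TRUE)
    aln[, `:=`(base_chrom = sp[[1]], hap_suffix = sp[[2]])]
    vpos_by_chrom <- split(genome$variants$pos, genome$variants$chrom)
    aln[, n_var := {
      vp <- vpos_by_chrom[[base_chrom[1]]]
      if (is.null(vp)) 0L
      else findInterval(ref_end, vp) - findInterval(ref_start - 1L, vp)
    }, by = base_chrom]
    aln[, xb_tag := sprintf(
      "XB:Z:%s#%s,%d,%s,%d",
      base_chrom, data.table::fifelse(hap_suffix == "0", "1", "0"),
      ref_start, sam_strand, as_score - 4L * n_var
    )]
  } else {
    aln[, xb_tag := NA_character_]
  }

  # ---- SAM serialization ---------------------------------------------------
  data.table::setorder(aln, mol, copy, side, read_start)
  aln[, primary := read_start == read_start[1], by = .(mol, copy, side)]
  aln[, flag := 1L + data.table::fifelse(side == 1L, 64L, 128L) +
        data.table::fifelse(sam_strand == "-", 16L, 0L) +
        data.table::fifelse(primary, 0L, 2048L)]
  aln[, cigar := .sim_cigar(lead, mid, trail)]
  sam_body <- aln[, paste(
    read_id, flag, chrom, ref_start, 60L, cigar, "*", 0L, 0L, "*", "*",
    data.table::fifelse(is.na(xb_tag), paste0("AS:i:", as_score),
                        paste0("AS:i:", as_score, "\t", xb_tag)),
    sep = "\t")]
  sam_header <- c(
    "@HD\tVN:1.6\tGO:query",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chromsizes),
            genome$chromsizes)
  )

  # ---- per-read-pair truth -------------------------------------------------
  truth <- truth_mol[copies, on = "mol"]
  truth[, `:=`(pos1 = pmax(pos1 + d1, 1L), pos2 = pmax(pos2 + d2, 1L),
               dup_group = mol, pair_type = "UU")]
  if (config$diploid) {
    truth[, hap := mol_hap[mol]]
    # does the reported side overlap a planted variant?
    side_span <- aln[primary == TRUE,
                     .(read_id, side, base_chrom, ref_start, ref_end, n_var)]
    sp1 <- side_span[side == 1L]
    sp2 <- side_span[side == 2L]
    truth[sp1, on = "read_id", has_snv1 := i.n_var > 0L]
    truth[sp2, on = "read_id", has_snv2 := i.n_var > 0L]
  } else {
    truth[, `:=`(hap = NA_integer_, has_snv1 = NA, has_snv2 = NA)]
  }
  truth[, `:=`(readID = read_id, d1 = NULL, d2 = NULL, read_id = NULL)]
  truth <- flip_pairs(truth, genome$chromsizes)
  data.table::setcolorder(truth, c(
    "readID", "chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2",
    "pair_type", "mol", "copy", "dup_group", "class", "n_junctions",
    "hap", "has_snv1", "has_snv2"
  ))

  list(truth = truth[], sam = c(sam_header, sam_body),
       genome = genome, config = config)
}
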