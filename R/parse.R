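#' Parse configuration
#'
#' Tunable parameters governing how chimeric alignments are turned into
#' contact pairs.
#'
#' @param min_mapq Minimum mapping quality for a segment to count as uniquely
#'   mapped (class `U`); below it the segment is classed multi-mapping (`M`).
#' @param max_molecule_size Maximum genomic distance (bp) between the 5' ends
#'   of the two candidate alignments for single-ligation rescue; the typical
#'   sequenced molecule size.
#' @param max_inter_align_gap Longest run (bp) of unaligned read sequence
#'   tolerated between chained segments before an unmapped null segment is
#'   recorded in its place.
#' @param walk_policy How molecules with two or more ligation junctions are
#'   reported: `"mask"` (one `WW` record with null sides), `"all"` (one
#'   record per junction), `"5unique"`/`"5any"` (the 5'-most unique/any
#'   segment of each read side), or `"3unique"`/`"3any"` (3'-most).
#' @param flip Arrange each emitted pair so the genomically lower side comes
#'   first (see [flip_pairs()]).
#' @param extra_columns Optional output columns, any of `"mapq1"`, `"mapq2"`,
#'   `"score1"`, `"score2"`, `"XB1"`, `"XB2"`.  Under `walk_policy = "all"` a
#'   `walk_pair_index` column with the junction ordinal is always added.
#' @return A list of class `parse_config`.
#' @export
parse_config <- function(min_mapq = 1L,
                         max_molecule_size = 750L,
                         max_inter_align_gap = 20L,
                         walk_policy = c("5unique", "mask", "all", "5any",
                                         "3unique", "3any"),
                         flip = TRUE,
                         extra_columns = character()) {
  walk_policy <- match.arg(walk_policy)
  stopifnot(min_mapq >= 0L, max_molecule_size > 0L, max_inter_align_gap >= 0L)
  allowed <- c("mapq1", "mapq2", "score1", "score2", "XB1", "XB2")
  bad <- setdiff(extra_columns, allowed)
  if (length(bad)) stop("unknown extra columns: ", paste(bad, collapse = ", "))
  structure(
    list(min_mapq = as.integer(min_mapq),
         max_molecule_size = as.integer(max_molecule_size),
         max_inter_align_gap = as.integer(max_inter_align_gap),
         walk_policy = walk_policy,
         flip = isTRUE(flip),
         extra_columns = extra_columns),
    class = "parse_config"
  )
}

# ---- segment chains ---------------------------------------------------------

# A segment row: null, chrom, sam_strand, ref_start, ref_end, mapq,
# read_start, read_end, class, score, xb.  "Own view" = the segment as its
# own read reported it; the "opposite" frame flips the strand and takes the
# other end as the 5' position.
.null_segment <- function(read_start = NA_integer_, read_end = NA_integer_) {
  data.table::data.table(
    null = TRUE, chrom = .NULL_CHROM, sam_strand = .NULL_STRAND,
    ref_start = NA_integer_, ref_end = NA_integer_, mapq = NA_integer_,
    read_start = read_start, read_end = read_end, class = "N",
    score = NA_integer_, xb = NA_character_
  )
}

.seg_view <- function(seg, opposite = FALSE) {
  if (isTRUE(seg$null)) {
    return(list(chrom = .NULL_CHROM, pos = .NULL_POS, strand = .NULL_STRAND,
                class = "N", mapq = NA_integer_, score = NA_integer_,
                xb = NA_character_))
  }
  strand <- if (opposite) .other_strand(seg$sam_strand) else seg$sam_strand
  list(chrom = seg$chrom,
       pos = if (strand == "+") seg$ref_start else seg$ref_end,
       strand = strand, class = seg$class, mapq = seg$mapq,
       score = seg$score, xb = seg$xb)
}

.null_view <- function() .seg_view(.null_segment())

#' Build the ordered segment chain of one read side
#'
#' Orders the mapped, non-secondary alignments of one side along the read,
#' resolves overlapping read spans (higher mapping quality wins, then the
#' longer span, then the 5'-most), and inserts null segments for unaligned
#' gaps longer than `max_inter_align_gap` — including a leading gap, which
#' represents an unmapped 5' fragment of the molecule.  A side without any
#' mapped alignment yields a single null segment.
#'
#' @param side_alignments Alignment rows of one side (see [read_sam()]).
#' @param config A [parse_config()].
#' @return `data.table` of segments ordered 5' to 3' along the read.
#' @export
build_side_chain <- function(side_alignments, config) {
  a <- side_alignments[is_mapped & !is_secondary]
  if (!nrow(a)) return(.null_segment())
  a <- a[order(read_start, read_end)]
  keep <- rep(TRUE, nrow(a))
  last <- 1L
  i <- 2L
  while (i <= nrow(a)) {
    if (a$read_start[i] < a$read_end[last]) {
      # overlapping read spans: keep higher mapq, then longer, then 5'-most
      len_last <- a$read_end[last] - a$read_start[last]
      len_i <- a$read_end[i] - a$read_start[i]
      winner_i <- (a$mapq[i] > a$mapq[last]) ||
        (a$mapq[i] == a$mapq[last] && len_i > len_last)
      if (winner_i) {
        keep[last] <- FALSE
        last <- i
      } else {
        keep[i] <- FALSE
      }
    } else {
      last <- i
    }
    i <- i + 1L
  }
  a <- a[keep]
  segs <- data.table::data.table(
    null = FALSE, chrom = a$chrom, sam_strand = a$strand,
    ref_start = a$ref_start, ref_end = a$ref_end, mapq = a$mapq,
    read_start = a$read_start, read_end = a$read_end,
    class = data.table::fifelse(a$mapq >= config$min_mapq, "U", "M"),
    score = a$score, xb = a$xb
  )
  out <- vector("list", 2L * nrow(segs))
  prev_end <- 0L
  k <- 0L
  for (j in seq_len(nrow(segs))) {
    if (segs$read_start[j] - prev_end > config$max_inter_align_gap) {
      k <- k + 1L
      out[[k]] <- .null_segment(prev_end, segs$read_start[j])
    }
    k <- k + 1L
    out[[k]] <- segs[j]
    prev_end <- segs$read_end[j]
  }
  data.table::rbindlist(out[seq_len(k)])
}

#' Build both segment chains of a read bundle
#' @param bundle Alignment rows of one read (both sides).
#' @param config A [parse_config()].
#' @return List with elements `side1` and `side2`.
#' @export
build_chains <- function(bundle, config) {
  list(side1 = build_side_chain(bundle[side == 1L], config),
       side2 = build_side_chain(bundle[side == 2L], config))
}

# ---- readthrough collapse ---------------------------------------------------

.segments_match <- function(x, y) {
  !isTRUE(x$null) && !isTRUE(y$null) &&
    x$chrom == y$chrom &&
    x$sam_strand != y$sam_strand &&
    x$ref_start <= y$ref_end && y$ref_start <= x$ref_end
}

#' Merge the two side chains of a molecule, collapsing readthrough duplicates
#'
#' When sequencing reads past the end of the molecule, the 3' portions of the
#' two mates cover the same ligation fragments, producing duplicated
#' alignments.  The two chains are assembled into a single molecule-ordered
#' chain (side 1 from 5' to 3', then side 2 reversed); the longest suffix of
#' side 1 whose segments genomically coincide with the leading segments of
#' the reversed side-2 chain (same chromosome, opposite SAM strands,
#' reference spans overlapping) is merged so each ligation fragment appears
#' once.  Ties are broken toward keeping the 5'-most (side 1) copy.
#'
#' Each merged segment carries two reporting frames: `fwd` (the molecule read
#' in side 1's direction) and `rev` (read from the opposite end, side 2's
#' direction).  A fragment covered by both mates keeps each mate's own
#' coordinates for the corresponding frame.
#'
#' @param chain1,chain2 Segment chains from [build_side_chain()].
#' @param config A [parse_config()].
#' @return `data.table` of merged molecule segments with `fwd_*` and `rev_*`
#'   view columns.
#' @export
collapse_readthrough <- function(chain1, chain2, config) {
  n1 <- nrow(chain1)
  n2 <- nrow(chain2)
  # a side that is entirely unmapped carries no molecule segments of its own
  c1 <- if (n1 == 1L && chain1$null[1]) chain1[0] else chain1
  c2 <- if (n2 == 1L && chain2$null[1]) chain2[0] else chain2
  n1 <- nrow(c1)
  n2 <- nrow(c2)
  revb <- if (n2) c2[n2:1] else c2
  k <- min(n1, n2)
  while (k > 0L) {
    ok <- TRUE
    for (i in seq_len(k)) {
      if (!.segments_match(c1[n1 - k + i], revb[i])) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
    k <- k - 1L
  }
  rows <- vector("list", n1 + n2 - k)
  m <- 0L
  for (j in seq_len(n1)) {
    m <- m + 1L
    overlap_i <- j - (n1 - k)  # >0 when this side-1 segment was also read by side 2
    rev_rep <- if (overlap_i >= 1L && overlap_i <= n2) revb[overlap_i] else c1[j]
    rows[[m]] <- .merged_row(c1[j], fwd_opposite = FALSE,
                             rev_seg = rev_rep,
                             rev_opposite = !(overlap_i >= 1L))
  }
  if (n2 > k) {
    for (i in (k + 1L):n2) {
      m <- m + 1L
      rows[[m]] <- .merged_row(revb[i], fwd_opposite = TRUE,
                               rev_seg = revb[i], rev_opposite = FALSE)
    }
  }
  if (!m) {
    # both sides fully unmapped
    m <- 1L
    rows[[1]] <- .merged_row(.null_segment(), FALSE, .null_segment(), FALSE)
  }
  data.table::rbindlist(rows[seq_len(m)])
}

.merged_row <- function(fwd_seg, fwd_opposite, rev_seg, rev_opposite) {
  f <- .seg_view(fwd_seg, opposite = fwd_opposite)
  r <- .seg_view(rev_seg, opposite = rev_opposite)
  data.table::data.table(
    null = isTRUE(fwd_seg$null), chrom = fwd_seg$chrom,
    fwd_strand = f$strand, fwd_pos = f$pos, fwd_class = f$class,
    fwd_mapq = f$mapq, fwd_score = f$score, fwd_xb = f$xb,
    rev_strand = r$strand, rev_pos = r$pos, rev_class = r$class,
    rev_mapq = r$mapq, rev_score = r$score, rev_xb = r$xb
  )
}

.merged_view <- function(merged_row, frame = c("fwd", "rev")) {
  frame <- match.arg(frame)
  p <- function(nm) merged_row[[paste0(frame, "_", nm)]]
  list(chrom = if (merged_row$null) .NULL_CHROM else merged_row$chrom,
       pos = if (merged_row$null) .NULL_POS else p("pos"),
       strand = if (merged_row$null) .NULL_STRAND else p("strand"),
       class = p("class"), mapq = p("mapq"), score = p("score"),
       xb = p("xb"))
}

# ---- rescue and walks -------------------------------------------------------

#' Rescue a single ligation sequenced as three alignments
#'
#' When one mate carries two segments (5' "red", 3' "green") and the other a
#' single segment ("blue"), and green and blue are two reads of the same
#' ligation fragment — same chromosome, opposite SAM strands, 5' ends within
#' `max_molecule_size` — the molecule represents a single ligation and the
#' true contact is (red, blue).  Otherwise the molecule is a multi-junction
#' walk and `NULL` is returned.
#'
#' @param chain1,chain2 Segment chains; one must hold exactly two mapped
#'   unique segments and the other exactly one.
#' @param config A [parse_config()].
#' @return List with `side1`, `side2` segment views and `rescued_side`
#'   (1 or 2), or `NULL` when the rescue conditions fail.
#' @export
rescue_single_ligation <- function(chain1, chain2, config) {
  ok_chain <- function(ch, n) {
    nrow(ch) == n && !any(ch$null) && all(ch$class == "U")
  }
  if (ok_chain(chain1, 2L) && ok_chain(chain2, 1L)) {
    two <- chain1; one <- chain2; rescued_side <- 1L
  } else if (ok_chain(chain1, 1L) && ok_chain(chain2, 2L)) {
    two <- chain2; one <- chain1; rescued_side <- 2L
  } else {
    return(NULL)
  }
  green <- two[2L]
  blue <- one[1L]
  gv <- .seg_view(green)
  bv <- .seg_view(blue)
  if (green$chrom == blue$chrom &&
      green$sam_strand != blue$sam_strand &&
      abs(gv$pos - bv$pos) <= config$max_molecule_size) {
    red <- .seg_view(two[1L])
    red$class <- "R"
    if (rescued_side == 1L) {
      list(side1 = red, side2 = bv, rescued_side = 1L)
    } else {
      list(side1 = bv, side2 = red, rescued_side = 2L)
    }
  } else {
    NULL
  }
}

#' Report a multi-junction walk according to a walk policy
#'
#' @param merged Molecule chain from [collapse_readthrough()].
#' @param chain1,chain2 The per-side chains (used by the `5*`/`3*` policies,
#'   which choose within each read side).
#' @param config A [parse_config()]; `config$walk_policy` selects the policy.
#' @return List of `(side1, side2, walk_pair_index)` emission triples.
#' @export
expand_walk <- function(merged, chain1, chain2, config) {
  policy <- config$walk_policy
  t <- nrow(merged)
  if (policy == "mask") {
    s <- .null_view()
    s$class <- "W"
    return(list(list(side1 = s, side2 = s, walk_pair_index = NA_integer_)))
  }
  if (policy == "all") {
    return(lapply(seq_len(t - 1L), function(i) {
      list(side1 = .merged_view(merged[i], "fwd"),
           side2 = .merged_view(merged[i + 1L], "rev"),
           walk_pair_index = i)
    }))
  }
  from_5p <- policy %in% c("5unique", "5any")
  unique_only <- policy %in% c("5unique", "3unique")
  pick <- function(chain) {
    idx <- seq_len(nrow(chain))
    if (!from_5p) idx <- rev(idx)
    if (unique_only) idx <- idx[chain$class[idx] == "U"]
    if (!length(idx)) return(NULL)
    chain[idx[1]]
  }
  s1 <- pick(chain1)
  s2 <- pick(chain2)
  if (!unique_only) {
    # one side entirely unmapped: the *any policies may take both segments
    # from the mapped side (in molecule order)
    mapped1 <- sum(!chain1$null)
    mapped2 <- sum(!chain2$null)
    if (mapped1 == 0L && mapped2 >= 2L) {
      idx <- if (from_5p) c(1L, 2L) else c(nrow(chain2) - 1L, nrow(chain2))
      return(list(list(side1 = .seg_view(chain2[idx[1]]),
                       side2 = .seg_view(chain2[idx[2]], opposite = TRUE),
                       walk_pair_index = NA_integer_)))
    }
    if (mapped2 == 0L && mapped1 >= 2L) {
      idx <- if (from_5p) c(1L, 2L) else c(nrow(chain1) - 1L, nrow(chain1))
      return(list(list(side1 = .seg_view(chain1[idx[1]]),
                       side2 = .seg_view(chain1[idx[2]], opposite = TRUE),
                       walk_pair_index = NA_integer_)))
    }
  }
  list(list(
    side1 = if (is.null(s1)) .null_view() else .seg_view(s1),
    side2 = if (is.null(s2)) .null_view() else .seg_view(s2),
    walk_pair_index = NA_integer_
  ))
}

#' Two-character pair type from per-side mapping classes
#'
#' Classes: `N` unmapped, `M` multi-mapping (below the mapq threshold),
#' `U` unique, `R` rescued, `W` masked walk, `D` duplicate.  With
#' `flip = TRUE` the lesser class (ordered N < M < mapped) is put first, as
#' the canonical orientation of pairs with unmapped or multi-mapped sides.
#'
#' @param class1,class2 Per-side class letters.
#' @param flip Apply the class-ordering convention.
#' @return Character vector of two-letter codes.
#' @export
assign_pair_type <- function(class1, class2, flip = FALSE) {
  if (flip) {
    t1 <- .class_tier(class1)
    t2 <- .class_tier(class2)
    swap <- t1 > t2
    tmp <- class1[swap]
    class1[swap] <- class2[swap]
    class2[swap] <- tmp
  }
  paste0(class1, class2)
}

.class_tier <- function(cls) {
  data.table::fcase(
    cls == "N", 0L,
    cls == "M", 1L,
    default = 2L
  )
}

# ---- bundle-level parse -----------------------------------------------------

# assemble one emission triple into a record row (list)
.emit_record <- function(read_id, s1, s2, walk_pair_index = NA_integer_) {
  list(
    readID = read_id,
    chrom1 = s1$chrom, pos1 = as.integer(s1$pos), strand1 = s1$strand,
    chrom2 = s2$chrom, pos2 = as.integer(s2$pos), strand2 = s2$strand,
    class1 = s1$class, class2 = s2$class,
    mapq1 = s1$mapq, mapq2 = s2$mapq,
    score1 = s1$score, score2 = s2$score,
    XB1 = s1$xb, XB2 = s2$xb,
    walk_pair_index = as.integer(walk_pair_index)
  )
}

#' Parse one read bundle into contact records
#'
#' Composition of the parse steps: per-side chain building, readthrough
#' collapse, single-ligation rescue, and walk expansion; see the individual
#' operations for the rules.  Records are returned unflipped with raw class
#' columns; [parse_pairs()] applies typing, extra-column selection and
#' flipping.
#'
#' @param bundle Alignment rows of one read.
#' @param config A [parse_config()].
#' @return List of emission rows (internal layout).
#' @export
parse_bundle <- function(bundle, config) {
  read_id <- bundle$qname[1]
  chains <- build_chains(bundle, config)
  c1 <- chains$side1
  c2 <- chains$side2
  if (nrow(c1) <= 1L && nrow(c2) <= 1L) {
    return(list(.emit_record(read_id, .seg_view(c1[1L]), .seg_view(c2[1L]))))
  }
  m_total <- sum(!c1$null) + sum(!c2$null)
  if (m_total == 3L) {
    rescued <- rescue_single_ligation(c1, c2, config)
    if (!is.null(rescued)) {
      return(list(.emit_record(read_id, rescued$side1, rescued$side2)))
    }
  }
  merged <- collapse_readthrough(c1, c2, config)
  t <- nrow(merged)
  if (t == 1L) {
    return(list(.emit_record(read_id,
                             .merged_view(merged[1L], "fwd"),
                             .merged_view(merged[1L], "rev"))))
  }
  if (t == 2L) {
    return(list(.emit_record(read_id,
                             .merged_view(merged[1L], "fwd"),
                             .merged_view(merged[2L], "rev"))))
  }
  emissions <- expand_walk(merged, c1, c2, config)
  lapply(emissions, function(e) {
    .emit_record(read_id, e$side1, e$side2, e$walk_pair_index)
  })
}

#' Parse SAM alignments into a `.pairs` table
#'
#' The main entry point of contact extraction: takes name-grouped SAM text
#' produced by a local aligner run with independent mate alignment, and
#' returns a `.pairs` header and record table.  Simple two-alignment bundles
#' take a vectorised fast path; chimeric bundles go through [parse_bundle()].
#'
#' @param sam Path to a SAM file, character vector of SAM lines, or the list
#'   returned by [read_sam()].
#' @param chromsizes Named integer vector of chromosome lengths (canonical
#'   order), or the path to a chromsizes TSV.
#' @param config A [parse_config()].
#' @param command Provenance string recorded in the output header.
#' @return List with `header` ([pairs_header]) and `pairs` (`data.table`).
#' @export
parse_pairs <- function(sam, chromsizes, config = parse_config(),
                        command = "pairsuite parse") {
  if (is.character(chromsizes) && is.null(names(chromsizes)) &&
      length(chromsizes) == 1L) {
    chromsizes <- read_chromsizes(chromsizes)
  }
  sam_in <- if (is.list(sam) && !is.data.frame(sam)) sam else read_sam(sam)
  aln <- sam_in$alignments
  extras <- config$extra_columns
  if (config$walk_policy == "all") {
    extras <- union(extras, "walk_pair_index")
  }
  out_cols <- c(.PAIRS_CORE_COLUMNS, extras)
  header <- pairs_header(chromsizes, columns = out_cols,
                         samheader = sam_in$samheader,
                         provenance = command)
  if (!nrow(aln)) {
    empty <- data.table::as.data.table(
      stats::setNames(rep(list(character()), length(out_cols)), out_cols)
    )
    empty[, `:=`(pos1 = integer(), pos2 = integer())]
    return(list(header = header, pairs = empty[]))
  }
  unknown <- setdiff(unique(aln$chrom[aln$is_mapped]), names(chromsizes))
  if (length(unknown)) {
    stop("alignment chromosome(s) not in chromsizes: ",
         paste(unknown, collapse = ", "))
  }
  aln <- aln[is_secondary == FALSE]
  aln[, bundle := data.table::rleid(qname)]
  firsts <- aln$qname[!duplicated(aln$bundle)]
  if (anyDuplicated(firsts)) {
    stop("input not name-grouped: read id '",
         firsts[duplicated(firsts)][1], "' reappears after a different id")
  }

  # fast path: exactly one non-supplementary alignment per side, no leading
  # unaligned gap longer than the inter-alignment tolerance
  per_side <- aln[, .(
    n = .N,
    any_sup = any(is_supplementary),
    gap_ok = all(!is_mapped | read_start <= config$max_inter_align_gap)
  ), by = .(bundle, side)]
  per_bundle <- per_side[, .(
    simple = .N == 2L && all(n == 1L) && !any(any_sup) && all(gap_ok)
  ), by = bundle]
  simple_ids <- per_bundle[simple == TRUE, bundle]

  records <- list()
  if (length(simple_ids)) {
    fast <- aln[bundle %in% simple_ids]
    data.table::setorder(fast, bundle, side)
    s1 <- fast[side == 1L]
    s2 <- fast[side == 2L]
    side_view <- function(s) {
      mapped <- s$is_mapped
      data.table::data.table(
        chrom = data.table::fifelse(mapped, s$chrom, .NULL_CHROM),
        pos = data.table::fifelse(
          mapped,
          data.table::fifelse(s$strand == "+", s$ref_start, s$ref_end),
          .NULL_POS),
        strand = data.table::fifelse(mapped, s$strand, .NULL_STRAND),
        class = data.table::fifelse(
          mapped,
          data.table::fifelse(s$mapq >= config$min_mapq, "U", "M"),
          "N"),
        mapq = data.table::fifelse(mapped, s$mapq, NA_integer_),
        score = data.table::fifelse(mapped, s$score, NA_integer_),
        xb = data.table::fifelse(mapped, s$xb, NA_character_)
      )
    }
    v1 <- side_view(s1)
    v2 <- side_view(s2)
    records[[1]] <- data.table::data.table(
      readID = s1$qname,
      chrom1 = v1$chrom, pos1 = v1$pos, strand1 = v1$strand,
      chrom2 = v2$chrom, pos2 = v2$pos, strand2 = v2$strand,
      class1 = v1$class, class2 = v2$class,
      mapq1 = v1$mapq, mapq2 = v2$mapq,
      score1 = v1$score, score2 = v2$score,
      XB1 = v1$xb, XB2 = v2$xb,
      walk_pair_index = NA_integer_
    )
  }
  complex_ids <- setdiff(unique(aln$bundle), simple_ids)
  if (length(complex_ids)) {
    chunks <- split(aln[bundle %in% complex_ids], by = "bundle")
    rows <- unlist(lapply(chunks, parse_bundle, config = config),
                   recursive = FALSE)
    records[[length(records) + 1L]] <- data.table::rbindlist(rows)
  }
  pairs <- data.table::rbindlist(records)
  # restore input read order (stable within a read: emission order)
  pairs[, bundle := match(readID, unique(aln$qname))]
  pairs[, .row := .I]
  data.table::setorder(pairs, bundle, .row)
  pairs[, c("bundle", ".row") := NULL]

  pairs[, pair_type := assign_pair_type(class1, class2)]
  pairs[, `:=`(class1 = NULL, class2 = NULL)]
  data.table::setcolorder(pairs, .PAIRS_CORE_COLUMNS)
  drop <- setdiff(names(pairs), out_cols)
  if (length(drop)) pairs[, (drop) := NULL]
  if (config$flip) {
    pairs <- flip_pairs(pairs, chromsizes)
  }
  list(header = header, pairs = pairs[])
}
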